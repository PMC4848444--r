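#' Fundus image container
#'
#' A colour fundus photograph: an RGB raster (0..255 per channel) showing a
#' bright circular retina on a dark background, together with the retina
#' circle geometry, the AREDS severity category and an image-quality flag.
#'
#' AREDS categories: 1 = no AMD, 2 = mild (hard drusen), 3 = moderate
#' (soft drusen), 4 = advanced (hemorrhage / geographic atrophy).
#'
#' @param pixels numeric H x W x 3 array, values in 0..255.
#' @param center retina circle centre, `c(row, col)` in pixels.
#' @param radius retina circle radius in pixels.
#' @param label AREDS category in 1..4, or `NA` if unknown.
#' @param quality `"good"`, `"poor"` or `NA`.
#' @param id image identifier string.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, center, radius, label = NA, quality = NA,
                         id = "img") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (d[1] < 64L || d[2] < 64L)
    stop("raster must be at least 64 x 64")
  if (center[1] - radius < 1 || center[1] + radius > d[1] ||
      center[2] - radius < 1 || center[2] + radius > d[2])
    stop("retina circle does not fit inside the raster")
  if (!is.na(label) && !label %in% 1:4)
    stop("label must be an AREDS category in 1..4 or NA")
  if (!is.na(quality) && !quality %in% c("good", "poor"))
    stop("quality must be 'good', 'poor' or NA")
  structure(
    list(pixels = pixels, center = as.numeric(center),
         radius = as.numeric(radius), label = label,
         quality = quality, id = id),
    class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<fundus_image '%s'> %dx%d, circle (%.1f, %.1f) r=%.1f, label=%s, quality=%s\n",
    x$id, d[1], d[2], x$center[1], x$center[2], x$radius,
    ifelse(is.na(x$label), "?", x$label),
    ifelse(is.na(x$quality), "?", x$quality)))
  invisible(x)
}

#' Read a dataset from a manifest CSV
#'
#' The manifest has columns `id, path, label, quality`; paths are resolved
#' relative to the manifest location.  Images are 8-bit RGB PNGs; the
#' retina circle is located automatically with [detect_retina_circle()].
#'
#' @param manifest path to a manifest CSV.
#' @return a list of `fundus_image` objects.
#' @export
read_dataset <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "path", "label", "quality")
  if (!all(need %in% names(man)))
    stop("manifest must have columns id, path, label, quality")
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    px <- png::readPNG(p)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    px <- px[, , 1:3, drop = FALSE] * 255
    circ <- detect_retina_circle(px)
    fundus_image(px, circ$center, circ$radius,
                 label = man$label[i], quality = man$quality[i],
                 id = man$id[i])
  })
}
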