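# Preprocessing: retina localisation, inscribed-square ROI, illumination
# normalisation and contrast enhancement on the green channel.

#' Locate the retina circle in a raw RGB raster
#'
#' The retina is the bright disc on a dark background.  Pixels whose
#' maximum channel intensity exceeds 10% of the image maximum (and an
#' absolute floor of 20 intensity levels) are thresholded, the largest
#' connected component is taken, and an enclosing circle is fitted at the
#' component centroid.  The radius is clipped so the circle fits inside
#' the raster.
#'
#' @param pixels numeric H x W x 3 array (0..255).
#' @return a list with `center` (`c(row, col)`) and `radius` (pixels).
#' @export
detect_retina_circle <- function(pixels) {
  if (inherits(pixels, "fundus_image")) pixels <- pixels$pixels
  mx <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  top <- max(mx)
  if (top < 20) stop("no retina detected")
  mask <- mx > pmax(0.1 * top, 20)
  if (!any(mask)) stop("no retina detected")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  comp <- which(lab == which.max(tab), arr.ind = TRUE)
  ctr <- colMeans(comp)
  r <- sqrt(max((comp[, 1] - ctr[1])^2 + (comp[, 2] - ctr[2])^2))
  d <- dim(mx)
  r <- min(r, ctr[1] - 1, d[1] - ctr[1], ctr[2] - 1, d[2] - ctr[2])
  list(center = as.numeric(ctr), radius = as.numeric(r))
}

#' Extract the inscribed-square region of interest
#'
#' The ROI is the axis-aligned square inscribed in the retina circle:
#' side `s` is the largest even integer not exceeding `radius * sqrt(2)`,
#' centred on the circle centre.  The normalised green channel (see
#' [normalize_illumination()]) is attached as `green_norm`.
#'
#' @param img a [fundus_image()].
#' @return an object of class `roi_image`: a list with `pixels`
#'   (S x S x 3), `green_norm` (S x S, enhanced green channel), `side`,
#'   and the originating `label`, `quality`, `id`.
#' @export
extract_roi <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  s <- floor(img$radius * sqrt(2))
  if (s %% 2 == 1) s <- s - 1
  if (s < 8) stop("ROI too small")
  half <- s / 2
  cr <- round(img$center[1]); cc <- round(img$center[2])
  rows <- (cr - half + 1):(cr + half)
  cols <- (cc - half + 1):(cc + half)
  d <- dim(img$pixels)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2]) {
    warning("retina circle partially outside raster; cropping ROI to raster")
    rows <- rows[rows >= 1 & rows <= d[1]]
    cols <- cols[cols >= 1 & cols <= d[2]]
  }
  px <- img$pixels[rows, cols, , drop = FALSE]
  gn <- normalize_illumination(px[, , 2])
  structure(
    list(pixels = px, green_norm = gn, side = dim(px)[1],
         label = img$label, quality = img$quality, id = img$id),
    class = "roi_image")
}

#' Normalise illumination and enhance contrast of the green channel
#'
#' The background illumination is estimated with a median filter whose
#' kernel is one-fourth the ROI side (forced odd) and subtracted; the
#' residual is doubled for contrast enhancement and shifted by the
#' midpoint of the 8-bit range (128) for display:
#' `out = 2 * (g - median_k(g)) + 128`, clipped to \[0, 255\] but kept as
#' real values for downstream feature computation.
#'
#' @param green numeric S x S matrix (0..255), the green channel of an ROI.
#' @return an S x S real matrix in \[0, 255\].
#' @export
normalize_illumination <- function(green) {
  if (inherits(green, "roi_image")) green <- green$pixels[, , 2]
  s <- min(dim(green))
  if (s < 8) stop("ROI side must be at least 8")
  k <- illumination_kernel_size(s)
  bg <- EBImage::medianFilter(green / 255, size = (k - 1) / 2) * 255
  clip_range(2 * (green - bg) + 128, 0, 255)
}

#' Median-filter kernel size used for illumination normalisation
#' @param side ROI side in pixels.
#' @return odd integer kernel size (one-fourth of the side, forced odd).
#' @export
illumination_kernel_size <- function(side) {
  k <- round(side / 4)
  if (k %% 2 == 0) k + 1 else k
}
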