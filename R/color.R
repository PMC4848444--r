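# Colour-histogram features over the RGB and L*a*b* spaces.

# sRGB (0..255) H x W x 3 array -> n x 3 matrix of L*, a*, b*.
rgb_to_lab <- function(pixels) {
  m <- cbind(as.vector(pixels[, , 1]),
             as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3])) / 255
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

.channel_hist <- function(v, lo, hi, bins) {
  v <- clip_range(v, lo, hi - 1e-9)
  h <- tabulate(floor((v - lo) / (hi - lo) * bins) + 1L, nbins = bins)
  h / sum(h)
}

#' Colour-histogram features
#'
#' Per-channel histograms over both colour spaces: R, G, B (range 0..256)
#' and L* (0..100), a*, b* (-110..110), each L1-normalised and
#' concatenated.  With the default 16 bins per channel this yields 96
#' features (48 per colour space), matching the pipeline's printed
#' dimensionality; `bins = 8` gives the compact 48-feature variant.
#'
#' @param roi an `roi_image` (or H x W x 3 array, 0..255).
#' @param bins bins per channel (default 16).
#' @return named numeric vector of length `6 * bins`.
#' @export
color_histograms <- function(roi, bins = 16) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  lab <- rgb_to_lab(px)
  h <- c(.channel_hist(px[, , 1], 0, 256, bins),
         .channel_hist(px[, , 2], 0, 256, bins),
         .channel_hist(px[, , 3], 0, 256, bins),
         .channel_hist(lab[, 1], 0, 100, bins),
         .channel_hist(lab[, 2], -110, 110, bins),
         .channel_hist(lab[, 3], -110, 110, bins))
  names(h) <- paste0(rep(c("R", "G", "B", "L", "a", "b"), each = bins),
                     "_b", rep(seq_len(bins), 6))
  h
}
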