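# Small shared helpers.

#' Clip values to a range
#' @param x numeric.
#' @param lo,hi range limits.
#' @return `x` with values outside `[lo, hi]` replaced by the limit.
#' @keywords internal
clip_range <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed
#'
#' All stochastic stages consume seeds derived from one master seed via a
#' fixed integer recurrence, so any stage (or any single synthetic image)
#' can be re-run in isolation.  Results stay below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param salt integer distinguishing the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, salt) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(salt) * 16807
  as.integer(s %% 2147483647L) + 1L
}

#' RMS contrast of an image
#'
#' Standard deviation of the green channel, the channel carrying most of
#' the lesion/vessel contrast in fundus photographs.
#'
#' @param pixels an H x W x 3 array (or a `fundus_image`).
#' @return a scalar.
#' @export
rms_contrast <- function(pixels) {
  if (inherits(pixels, "fundus_image")) pixels <- pixels$pixels
  stats::sd(pixels[, , 2])
}

# Gaussian blur of a single matrix or an H x W x 3 array (sigma in pixels).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  if (length(dim(x)) == 3L) {
    for (ch in 1:3) x[, , ch] <- gauss_blur(x[, , ch], sigma)
    return(x)
  }
  EBImage::gblur(x, sigma = sigma)
}
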