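# Local binary patterns (sign and magnitude components) with uniform
# mapping, computed over every raster of a wavelet stack.

# Neighbour offsets for R = 1, P = 8: p = 0 points east, then
# counterclockwise in image coordinates (rows grow downward, so
# counterclockwise means decreasing row).
.lbp_offsets <- local({
  p <- 0:7
  ang <- p * pi / 4
  cbind(dr = -sin(ang), dc = cos(ang))
})

# Interior view of x shifted by integer (dr, dc); x interior is rows/cols
# 2..(n-1).  Caller guarantees |dr|, |dc| <= 1.
.shift_interior <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  x[(2 + dr):(n - 1 + dr), (2 + dc):(m - 1 + dc), drop = FALSE]
}

# Neighbour value matrices (bilinear interpolation on the unit circle)
# for all interior pixels.  Returns a list of 8 matrices.
.lbp_neighbours <- function(x) {
  lapply(1:8, function(p) {
    dr <- .lbp_offsets[p, 1]; dc <- .lbp_offsets[p, 2]
    r0 <- floor(dr + 1e-9); c0 <- floor(dc + 1e-9)
    ar <- dr - r0; ac <- dc - c0
    if (abs(ar) < 1e-9 && abs(ac) < 1e-9) return(.shift_interior(x, r0, c0))
    (1 - ar) * (1 - ac) * .shift_interior(x, r0, c0) +
      (1 - ar) * ac * .shift_interior(x, r0, c0 + 1) +
      ar * (1 - ac) * .shift_interior(x, r0 + 1, c0) +
      ar * ac * .shift_interior(x, r0 + 1, c0 + 1)
  })
}

#' LBP codes of a raster
#'
#' Computes, for every interior pixel, the 8-bit local binary pattern
#' code at radius 1 with 8 neighbours sampled on the circle (diagonal
#' neighbours bilinearly interpolated at distance 1).  Neighbour `p = 0`
#' lies east of the centre; neighbours proceed counterclockwise, and bit
#' `p` has weight `2^p`.
#'
#' The `"sign"` component sets bit `p` when the neighbour is at least as
#' bright as the centre.  The `"magnitude"` component thresholds the
#' absolute centre-neighbour differences `m_p = |g_p - g_c|` against `c`,
#' which defaults to the mean of all `m_p` over the raster.
#'
#' Border pixels have no full neighbourhood and are skipped.
#'
#' @param x numeric matrix (side >= 3).
#' @param type `"sign"` or `"magnitude"`.
#' @param threshold magnitude threshold `c`; `NULL` (default) uses the
#'   raster mean of the `m_p`.
#' @return a list with `codes`, an (n-2) x (m-2) integer matrix of codes
#'   in 0..255, and `threshold` (the `c` actually used; `NA` for sign).
#' @export
lbp_codes <- function(x, type = c("sign", "magnitude"), threshold = NULL) {
  type <- match.arg(type)
  if (min(dim(x)) < 3) stop("raster too small for a 3 x 3 neighbourhood")
  gc <- .shift_interior(x, 0, 0)
  nb <- .lbp_neighbours(x)
  codes <- matrix(0L, nrow(gc), ncol(gc))
  if (type == "sign") {
    for (p in 1:8) codes <- codes + as.integer(nb[[p]] >= gc) * 2L^(p - 1L)
    thr <- NA_real_
  } else {
    mp <- lapply(nb, function(g) abs(g - gc))
    thr <- if (is.null(threshold)) mean(unlist(mp)) else threshold
    for (p in 1:8) codes <- codes + as.integer(mp[[p]] >= thr) * 2L^(p - 1L)
  }
  list(codes = codes, threshold = thr)
}

#' LBP sign code of a single 3 x 3 patch
#' @param patch numeric 3 x 3 matrix; the centre pixel is `patch[2, 2]`.
#' @return integer code in 0..255.
#' @export
lbp_sign_code <- function(patch) {
  stopifnot(all(dim(patch) == c(3, 3)))
  lbp_codes(patch, "sign")$codes[1, 1]
}

#' LBP magnitude code of a single 3 x 3 patch
#' @param patch numeric 3 x 3 matrix.
#' @param threshold magnitude threshold `c`.
#' @return integer code in 0..255.
#' @export
lbp_magnitude_code <- function(patch, threshold) {
  stopifnot(all(dim(patch) == c(3, 3)))
  lbp_codes(patch, "magnitude", threshold = threshold)$codes[1, 1]
}

# Map each 8-bit code to one of 59 bins: the 58 uniform patterns (at most
# two 0/1 transitions around the circle) in ascending code order, plus a
# catch-all bin 59.
.lbp_uniform_map <- local({
  transitions <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }
  u <- vapply(0:255, transitions, integer(1)) <= 2L
  map <- rep(59L, 256)
  map[u] <- seq_len(sum(u))
  map
})

#' Uniform-pattern histogram of LBP codes
#'
#' 59-bin histogram: bins 1..58 are the uniform patterns (ascending code
#' order), bin 59 collects all non-uniform codes.  L1-normalised; an
#' empty code matrix gives the all-zero vector.
#'
#' @param codes integer matrix of codes in 0..255.
#' @return numeric vector of length 59 summing to 1 (or all zero).
#' @export
lbp_histogram <- function(codes) {
  h <- tabulate(.lbp_uniform_map[as.integer(codes) + 1L], nbins = 59L)
  tot <- sum(h)
  if (tot == 0) return(numeric(59))
  h / tot
}

#' Multiresolution LBP features of one channel
#'
#' For each of the 17 rasters of a [wavelet_decompose()] stack, two
#' 59-bin uniform-pattern histograms are computed (sign first, then
#' magnitude), giving 17 x 2 x 59 = 2006 features in a fixed order:
#' rasters in stack order, sign before magnitude, bins ascending.
#' Rasters smaller than 3 x 3 contribute all-zero histograms.
#'
#' @param stack a `wavelet_stack`.
#' @return named numeric vector of length 2006.
#' @export
lbp_features <- function(stack) {
  stopifnot(inherits(stack, "wavelet_stack"))
  out <- lapply(seq_along(stack$images), function(i) {
    x <- stack$images[[i]]
    if (min(dim(x)) < 3) {
      hs <- numeric(59); hm <- numeric(59)
    } else {
      hs <- lbp_histogram(lbp_codes(x, "sign")$codes)
      hm <- lbp_histogram(lbp_codes(x, "magnitude")$codes)
    }
    v <- c(hs, hm)
    names(v) <- paste0(stack$tags[i], "_", rep(c("sign", "mag"), each = 59),
                       "_b", rep(1:59, 2))
    v
  })
  unlist(out)
}
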