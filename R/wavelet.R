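# Separable 2-D discrete wavelet transform used for the multiresolution
# LBP features.  The default filter is a truncated Battle-Lemarie
# (orthonormalised cubic-spline) pair; any orthogonal filter can be
# substituted.

# 24-tap truncation of the Battle-Lemarie cubic-spline scaling filter,
# obtained by frequency sampling of the orthonormalised refinement filter
# and projected so that sum(h) = sqrt(2) and the alternating sum is
# exactly 0 (constant inputs then give exactly-zero detail bands).
.bl24 <- c(
  -0.003671976433604985, -0.004293723646719511, 0.008411926037981398,
   0.008745410624113176, -0.017771872148972690, -0.017116199680936310,
   0.042278800272691510,  0.032141013281220080, -0.109826569556111000,
  -0.050141608860388740,  0.434133082421289700,  0.766190169570785600,
   0.434133082421289500, -0.050141608860388720, -0.109826569556111000,
   0.032141013281220060,  0.042278800272691460, -0.017116199680936300,
  -0.017771872148972700,  0.008745410624113175,  0.008411926037981386,
  -0.004293723646719506, -0.003671976433604979,  0.002246828181184618)

#' Wavelet filter pair
#'
#' Returns the lowpass/highpass analysis pair for a named orthogonal
#' wavelet.  `"bl24"` (default) is a 24-tap truncated Battle-Lemarie
#' cubic-spline filter; `"haar"` and `"d4"` (Daubechies extremal-phase,
#' 4 taps) are exact orthonormal alternatives.
#'
#' @param wavelet one of `"bl24"`, `"haar"`, `"d4"`.
#' @return list with `lowpass` and `highpass` numeric vectors.
#' @export
wavelet_filter <- function(wavelet = c("bl24", "haar", "d4")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    bl24 = .bl24,
    haar = rep(1 / sqrt(2), 2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L))  # quadrature mirror
  list(lowpass = h, highpass = g)
}

# Analysis operator: a (ceil(S/2) x S) matrix applying one filtering +
# dyadic downsampling step with the requested boundary handling.
dwt_operator <- function(S, filt, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  L <- length(filt)
  S2 <- ceiling(S / 2)
  op <- matrix(0, S2, S)
  off <- floor(L / 2)
  fold <- function(j) {
    if (mode == "periodic") return(((j - 1) %% S) + 1)
    # half-sample symmetric reflection, iterated until inside [1, S]
    while (j < 1 || j > S) {
      if (j < 1) j <- 1 - j
      if (j > S) j <- 2 * S + 1 - j
    }
    j
  }
  for (i in seq_len(S2)) {
    for (t in seq_len(L)) {
      j <- fold(2 * (i - 1) + t - off)
      op[i, j] <- op[i, j] + filt[t]
    }
  }
  op
}

#' Four-level 2-D wavelet decomposition
#'
#' Decomposes a real raster into the stack used by the multiresolution
#' LBP features: the original image plus, for each of four levels, the
#' approximation (A) and the horizontal (H), vertical (V) and diagonal
#' (D) detail images -- 17 rasters in total.  Each level halves the side
#' (rounded up).
#'
#' @param x numeric matrix, side at least 16.
#' @param wavelet filter name, see [wavelet_filter()].
#' @param mode boundary handling: `"symmetric"` (default) or
#'   `"periodic"` (exactly energy-preserving for orthonormal filters on
#'   even-sized inputs).
#' @param levels number of decomposition levels (default 4).
#' @return an object of class `wavelet_stack`: list with `images` (list
#'   of 17 matrices) and `tags` (e.g. `"original"`, `"L1_A"`, ...,
#'   `"L4_D"`).
#' @export
wavelet_decompose <- function(x, wavelet = "bl24",
                              mode = c("symmetric", "periodic"),
                              levels = 4) {
  mode <- match.arg(mode)
  if (min(dim(x)) < 16) stop("raster too small for 4-level decomposition")
  f <- wavelet_filter(wavelet)
  images <- list(x)
  tags <- "original"
  a <- x
  for (lev in seq_len(levels)) {
    nr <- nrow(a); nc <- ncol(a)
    Lr <- dwt_operator(nr, f$lowpass, mode)
    Hr <- dwt_operator(nr, f$highpass, mode)
    Lc <- dwt_operator(nc, f$lowpass, mode)
    Hc <- dwt_operator(nc, f$highpass, mode)
    A <- Lr %*% a %*% t(Lc)
    H <- Lr %*% a %*% t(Hc)   # detail along columns: horizontal structures
    V <- Hr %*% a %*% t(Lc)
    D <- Hr %*% a %*% t(Hc)
    images <- c(images, list(A, H, V, D))
    tags <- c(tags, paste0("L", lev, "_", c("A", "H", "V", "D")))
    a <- A
  }
  structure(list(images = images, tags = tags,
                 wavelet = wavelet, mode = mode),
            class = "wavelet_stack")
}

#' @export
print.wavelet_stack <- function(x, ...) {
  cat(sprintf("<wavelet_stack> %d rasters (%s, %s boundary)\n",
              length(x$images), x$wavelet, x$mode))
  invisible(x)
}
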