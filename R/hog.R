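# Histogram-of-oriented-gradients features on the RGB ROI.

#' HOG features
#'
#' Gradients are computed per channel with the 1-D point-centred
#' derivative kernel `[-1 0 1]` (horizontally and vertically); at each
#' pixel the channel with the largest gradient magnitude is kept.
#' Unsigned orientations are quantised into four 45-degree bins centred
#' on 0, 45, 90 and 135 degrees.  The image is divided into a 16 x 16
#' grid of cells (any remainder cropped); magnitude-weighted 4-bin
#' histograms per cell are grouped into 2 x 2-cell blocks with step 1
#' (15 x 15 blocks), each block L2-normalised with an epsilon guard.
#' Output: 15 x 15 x 4 cells x 4 bins = 3600 features.
#'
#' @param roi an `roi_image` or H x W x 3 array (0..255); side >= 32.
#' @param grid cell-grid size per side (default 16).
#' @return named numeric vector of length 3600 (for `grid = 16`).
#' @export
hog_features <- function(roi, grid = 16) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  n <- dim(px)[1]; m <- dim(px)[2]
  if (min(n, m) < 2 * grid) stop("ROI too small for the HOG cell grid")
  gx <- array(0, dim(px)); gy <- array(0, dim(px))
  gx[, 2:(m - 1), ] <- px[, 3:m, ] - px[, 1:(m - 2), ]
  gy[2:(n - 1), , ] <- px[3:n, , ] - px[1:(n - 2), , ]
  mag2 <- gx^2 + gy^2
  pick <- max.col(matrix(mag2, ncol = 3), ties.method = "first")
  idx <- cbind(seq_len(n * m), pick)
  gxs <- matrix(gx, ncol = 3)[idx]
  gys <- matrix(gy, ncol = 3)[idx]
  mag <- sqrt(gxs^2 + gys^2)
  theta <- atan2(gys, gxs) %% pi
  bin <- floor(((theta + pi / 8) %% pi) / (pi / 4)) + 1L

  cs_r <- floor(n / grid); cs_c <- floor(m / grid)
  row <- (seq_len(n * m) - 1L) %% n + 1L
  col <- (seq_len(n * m) - 1L) %/% n + 1L
  keep <- row <= cs_r * grid & col <= cs_c * grid
  cr <- (row[keep] - 1L) %/% cs_r
  cc <- (col[keep] - 1L) %/% cs_c
  cell_idx <- (cc * grid + cr) * 4L + bin[keep]  # 1..grid*grid*4
  acc <- numeric(grid * grid * 4L)
  sums <- rowsum(mag[keep], cell_idx)
  acc[as.integer(rownames(sums))] <- sums
  cells <- array(acc, c(4L, grid, grid))  # bin, cell-row, cell-col

  nb <- grid - 1L
  out <- numeric(nb * nb * 16L)
  nm <- character(nb * nb * 16L)
  eps <- 1e-6
  k <- 0L
  for (bc in seq_len(nb)) {
    for (br in seq_len(nb)) {
      v <- c(cells[, br:(br + 1L), bc:(bc + 1L)])
      v <- v / sqrt(sum(v^2) + eps^2)
      out[k + 1:16] <- v
      nm[k + 1:16] <- sprintf("blk%02d_%02d_c%d_o%d", br, bc,
                              rep(1:4, each = 4), rep(1:4, 4))
      k <- k + 16L
    }
  }
  names(out) <- nm
  out
}
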