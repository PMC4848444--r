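# Bag-of-visual-words over blob keypoints, emulating the SURF-style
# visual-context features: a determinant-of-Hessian scale-space detector
# with the 4-tuple descriptor (sign of Laplacian, orientation, scale,
# strength) that the vocabulary clusters on.

#' Detect blob keypoints in an ROI
#'
#' Scale-normalised determinant-of-Hessian detector on the L* channel of
#' the image converted to L*a*b* (rescaled to 0..255).  Scales span
#' `n_octaves` octaves with `n_layers` layers per octave starting at
#' sigma 1.6; scales whose support exceeds the image are skipped.  A
#' keypoint is a strict spatial 3 x 3 maximum of the response
#' `16 * ((s^2 Lxx)(s^2 Lyy) - (0.9 s^2 Lxy)^2)` exceeding `threshold`;
#' the factor 16 normalises the response so that an ideal Gaussian blob
#' of contrast `A` detected at its matched scale scores about `A^2`, so
#' the default threshold 600 retains blobs of contrast above ~25
#' intensity levels.
#'
#' @param roi an `roi_image` or H x W x 3 array (0..255).
#' @param n_octaves number of octaves (default 10).
#' @param n_layers layers per octave (default 3).
#' @param threshold Hessian response threshold (default 600).
#' @return a numeric matrix with one row per keypoint and columns
#'   `laplacian_sign`, `orientation`, `scale`, `strength` (plus `row`,
#'   `col` positions as attributes-free extra columns).
#' @export
detect_keypoints <- function(roi, n_octaves = 10, n_layers = 3,
                             threshold = 600) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else roi
  L <- matrix(rgb_to_lab(px)[, 1], dim(px)[1], dim(px)[2]) * 2.55
  n <- nrow(L); m <- ncol(L)
  kp <- list()
  for (o in 0:(n_octaves - 1)) {
    for (l in seq_len(n_layers)) {
      s <- 1.6 * 2^(o + (l - 1) / n_layers)
      if (6 * s > min(n, m) / 2) next
      G <- gauss_blur(L, s)
      Lxx <- matrix(0, n, m); Lyy <- Lxx; Lxy <- Lxx; Gx <- Lxx; Gy <- Lxx
      Lxx[, 2:(m - 1)] <- G[, 3:m] - 2 * G[, 2:(m - 1)] + G[, 1:(m - 2)]
      Lyy[2:(n - 1), ] <- G[3:n, ] - 2 * G[2:(n - 1), ] + G[1:(n - 2), ]
      Lxy[2:(n - 1), 2:(m - 1)] <-
        (G[3:n, 3:m] - G[3:n, 1:(m - 2)] -
         G[1:(n - 2), 3:m] + G[1:(n - 2), 1:(m - 2)]) / 4
      Gx[, 2:(m - 1)] <- (G[, 3:m] - G[, 1:(m - 2)]) / 2
      Gy[2:(n - 1), ] <- (G[3:n, ] - G[1:(n - 2), ]) / 2
      # normalised so an ideal Gaussian blob of contrast A detected at
      # its matched scale responds ~ A^2 (a matched blob has
      # s^2 Lxx = A/4 at the centre); the threshold is then a squared
      # blob-contrast scale on 0..255 images
      resp <- 16 * ((s^2 * Lxx) * (s^2 * Lyy) - (0.9 * s^2 * Lxy)^2)
      # strict maximum over the 3 x 3 spatial neighbourhood
      inr <- 2:(n - 1); inc <- 2:(m - 1)
      ismax <- resp[inr, inc] > threshold
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        ismax <- ismax & resp[inr, inc] > resp[inr + dr, inc + dc]
      }
      hit <- which(ismax, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      r <- hit[, 1] + 1L; c <- hit[, 2] + 1L
      ij <- cbind(r, c)
      lap <- sign(Lxx[ij] + Lyy[ij])
      ori <- atan2(Gy[ij], Gx[ij])
      kp[[length(kp) + 1]] <- cbind(
        laplacian_sign = lap, orientation = ori, scale = s,
        strength = resp[ij], row = r, col = c)
    }
  }
  if (length(kp) == 0)
    return(matrix(numeric(0), 0, 6, dimnames = list(NULL,
      c("laplacian_sign", "orientation", "scale", "strength", "row", "col"))))
  do.call(rbind, kp)
}

#' Build a visual-word vocabulary from keypoint descriptors
#'
#' K-means clustering of the 4-tuple descriptors (sign of Laplacian,
#' orientation, scale, strength) pooled over the AMD-positive training
#' images.  `K = 100` is used for binary tasks, `K = 300` for multiclass
#' tasks.  Descriptor columns are z-scored before clustering (the
#' scaling is stored and applied at assignment time).
#'
#' @param descriptors a matrix of descriptors (rows = keypoints) or a
#'   list of such matrices, with at least the four descriptor columns.
#' @param K vocabulary size.
#' @param seed integer seed for the clustering.
#' @return an object of class `surf_vocabulary`.
#' @export
build_surf_vocabulary <- function(descriptors, K = 100, seed = 1) {
  if (is.list(descriptors)) descriptors <- do.call(rbind, descriptors)
  d <- descriptors[, c("laplacian_sign", "orientation", "scale", "strength"),
                   drop = FALSE]
  if (nrow(d) < K)
    stop(sprintf("only %d keypoints available; reduce K below %d",
                 nrow(d), K))
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- scale(d, mu, sdv)
  set.seed(seed)
  km <- stats::kmeans(z, centers = K, nstart = 5, iter.max = 200,
                      algorithm = "Lloyd")
  structure(list(centroids = km$centers, K = K, seed = seed,
                 center = mu, scale = sdv),
            class = "surf_vocabulary")
}

#' @export
print.surf_vocabulary <- function(x, ...) {
  cat(sprintf("<surf_vocabulary> K=%d (seed %d)\n", x$K, x$seed))
  invisible(x)
}

#' Bag-of-visual-words histogram for one image
#'
#' Assigns each keypoint descriptor to its nearest vocabulary centroid
#' (Euclidean distance in the vocabulary's standardised space) and
#' returns the L1-normalised occurrence histogram.  Images without
#' keypoints yield the all-zero vector.
#'
#' @param descriptors keypoint descriptor matrix for one image (possibly
#'   0 rows).
#' @param vocab a [build_surf_vocabulary()] result.
#' @return numeric vector of length `vocab$K`.
#' @export
surf_features <- function(descriptors, vocab) {
  stopifnot(inherits(vocab, "surf_vocabulary"))
  h <- numeric(vocab$K)
  names(h) <- paste0("word", seq_len(vocab$K))
  if (is.null(descriptors) || nrow(descriptors) == 0) return(h)
  d <- descriptors[, c("laplacian_sign", "orientation", "scale", "strength"),
                   drop = FALSE]
  z <- scale(d, vocab$center, vocab$scale)
  ctr <- vocab$centroids
  d2 <- outer(rowSums(z^2), rowSums(ctr^2), "+") - 2 * z %*% t(ctr)
  nearest <- max.col(-d2, ties.method = "first")
  tab <- tabulate(nearest, nbins = vocab$K)
  h[] <- tab / sum(tab)
  h
}
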