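# Shared fixtures and independent oracles, built in code at test time.

# A plain bright disc on black background (known circle geometry).
make_disc_image <- function(side = 256, center = c(side / 2, side / 2),
                            radius = 100, rgb = c(200, 120, 50)) {
  d2 <- outer((seq_len(side) - center[1])^2,
              (seq_len(side) - center[2])^2, "+")
  inside <- d2 <= radius^2
  px <- array(0, c(side, side, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch] * inside
  px
}

# Small synthetic dataset reused across tests (memoised per session).
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- synth_spec(n_per_cell = matrix(4, 2, 4), image_side = 128,
                       seed = 11)
    .fixture_env$small <- generate_dataset(spec)
  }
  .fixture_env$small
}

small_features <- function() {
  if (is.null(.fixture_env$small_fs))
    .fixture_env$small_fs <- featurize_dataset(small_dataset()$images)
  .fixture_env$small_fs
}

one_roi <- function() {
  if (is.null(.fixture_env$roi))
    .fixture_env$roi <- extract_roi(small_dataset()$images[[10]])
  .fixture_env$roi
}

# ---- independent oracles -----------------------------------------------

# Per-pixel brute-force LBP (sign or magnitude): neighbours sampled on
# the unit circle with bilinear interpolation, code built term by term.
brute_lbp <- function(x, type = "sign", threshold = NULL) {
  n <- nrow(x); m <- ncol(x)
  interp <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    (1 - fr) * (1 - fc) * x[r0, c0] +
      (1 - fr) * fc * x[r0, min(c0 + 1, m)] +
      fr * (1 - fc) * x[min(r0 + 1, n), c0] +
      fr * fc * x[min(r0 + 1, n), min(c0 + 1, m)]
  }
  neigh <- function(i, j, p) {
    a <- p * pi / 4
    interp(i - sin(a), j + cos(a))
  }
  if (type == "magnitude" && is.null(threshold)) {
    mags <- c()
    for (i in 2:(n - 1)) for (j in 2:(m - 1)) for (p in 0:7)
      mags <- c(mags, abs(neigh(i, j, p) - x[i, j]))
    threshold <- mean(mags)
  }
  codes <- matrix(0L, n - 2, m - 2)
  for (i in 2:(n - 1)) for (j in 2:(m - 1)) {
    code <- 0L
    for (p in 0:7) {
      gp <- neigh(i, j, p)
      bit <- if (type == "sign") gp - x[i, j] >= 0 else
        abs(gp - x[i, j]) >= threshold
      code <- code + as.integer(bit) * 2L^p
    }
    codes[i - 1, j - 1] <- code
  }
  list(codes = codes, threshold = threshold)
}

# AUC as the normalised count of concordant positive/negative pairs
# (ties count one half).
pair_count_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exhaustive 2-means: best of all 2-partitions by total within-SS.
exhaustive_two_means <- function(z) {
  n <- nrow(z)
  best <- list(ss = Inf)
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (sum(grp) == 0 || sum(grp) == n) next
    ss <- 0
    for (g in 0:1) {
      zz <- z[grp == g, , drop = FALSE]
      ss <- ss + sum(sweep(zz, 2, colMeans(zz))^2)
    }
    if (ss < best$ss) best <- list(ss = ss, grp = grp)
  }
  best
}
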