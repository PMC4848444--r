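blob_data <- function(n_per = 20, centers = list(c(0, 0), c(8, 8)),
                      sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(ctr)
    cbind(rnorm(n_per, ctr[1], sd), rnorm(n_per, ctr[2], sd))))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(seq_along(centers), each = n_per))
}

test_that("SVM defaults carry the reference search grids", {
  expect_equal(eval(formals(train_svm)$gamma_grid),
               c(0.001, 0.01, 0.1, 1, 10))
  expect_equal(eval(formals(train_svm)$C_grid), c(1, 10, 50, 100))
  expect_equal(eval(formals(train_svm)$inner_k), 10)
})

test_that("a separable two-class problem is learned perfectly", {
  d <- blob_data(20)
  m <- train_svm(d$X, d$y, gamma_grid = c(0.01, 0.1), C_grid = c(1, 10),
                 inner_k = 4, seed = 2)
  pr <- predict(m, d$X)
  expect_equal(mean(pr$label == as.character(d$y)), 1)
  expect_equal(dim(pr$scores), c(40, 2))
})

test_that("one-vs-all 3-class SVM matches the nearest-centroid oracle", {
  d <- blob_data(15, centers = list(c(0, 0), c(10, 0), c(0, 10)), seed = 3)
  m <- train_svm(d$X, d$y, gamma_grid = 0.1, C_grid = 10, inner_k = 3,
                 seed = 1)
  set.seed(4)
  Xte <- d$X + rnorm(length(d$X), 0, 0.3)
  pr <- predict(m, Xte)
  centroids <- rbind(c(0, 0), c(10, 0), c(0, 10))
  oracle <- apply(Xte, 1, function(p)
    which.min(colSums((t(centroids) - p)^2)))
  expect_equal(pr$label, as.character(oracle))
})

test_that("SVM decision values ignore duplicated interior points", {
  d <- blob_data(20, seed = 5)
  m1 <- train_svm(d$X, d$y, gamma_grid = 0.1, C_grid = 10, inner_k = 4)
  # duplicate a point far inside its class region (not a support vector)
  far <- which.min(rowSums((d$X - matrix(c(0, 0), 40, 2, byrow = TRUE))^2))
  X2 <- rbind(d$X, d$X[far, ]); y2 <- c(d$y, d$y[far])
  m2 <- train_svm(X2, y2, gamma_grid = 0.1, C_grid = 10, inner_k = 4)
  grid <- cbind(runif(30, -2, 10), runif(30, -2, 10))
  p1 <- predict(m1, grid); p2 <- predict(m2, grid)
  expect_equal(p1$label, p2$label)
})

test_that("random-forest defaults follow the binary/multiclass convention", {
  d2 <- blob_data(15, seed = 6)
  m2 <- train_rf(d2$X, d2$y, seed = 1)
  expect_equal(m2$n_trees, 1000)
  d3 <- blob_data(10, centers = list(c(0, 0), c(8, 0), c(0, 8)), seed = 7)
  m3 <- train_rf(d3$X, d3$y, seed = 1)
  expect_equal(m3$n_trees, 2500)
  # mtry = floor(sqrt(p)); 266 features -> 16
  X <- matrix(rnorm(20 * 266), 20)
  m <- train_rf(X, rep(1:2, each = 10), n_trees = 50, seed = 1)
  expect_equal(m$mtry, 16)
})

test_that("random forest separates distant blobs on held-out data", {
  d <- blob_data(30, seed = 8)
  hold <- c(1:6, 31:36)
  m <- train_rf(d$X[-hold, ], d$y[-hold], n_trees = 500, seed = 2)
  pr <- predict(m, d$X[hold, ])
  expect_gt(mean(pr$label == as.character(d$y[hold])), 0.95)
  expect_equal(rowSums(pr$scores), rep(1, 12), tolerance = 1e-9)
})

test_that("prediction validates the feature dimension", {
  d <- blob_data(10, seed = 9)
  m <- train_rf(d$X, d$y, n_trees = 50, seed = 1)
  expect_error(predict(m, matrix(0, 2, 5)), "expected 2, received 5")
})

test_that("training and prediction are deterministic for a fixed seed", {
  d <- blob_data(15, sd = 2, seed = 10)
  m1 <- train_rf(d$X, d$y, n_trees = 300, seed = 4)
  m2 <- train_rf(d$X, d$y, n_trees = 300, seed = 4)
  expect_equal(predict(m1, d$X)$scores, predict(m2, d$X)$scores)
})
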