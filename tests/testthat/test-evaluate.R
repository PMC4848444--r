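test_that("stratified folds are balanced and reproducible", {
  y <- rep(1:4, c(79, 79, 65, 56))  # 279 samples
  f <- make_folds(y, k = 10, seed = 3)
  expect_true(all(table(f) %in% c(27, 28)))
  expect_length(f, 279)
  # stratification: each class spread over all folds
  for (cl in 1:4) expect_equal(length(unique(f[y == cl])), 10)
  expect_identical(f, make_folds(y, k = 10, seed = 3))
  expect_false(identical(f, make_folds(y, k = 10, seed = 4)))
})

test_that("k = n reduces to leave-one-out", {
  y <- rep(c("a", "b"), each = 6)
  f <- suppressWarnings(make_folds(y, k = 12, seed = 1))
  expect_equal(sort(unique(f)), 1:12)
  expect_true(all(table(f) == 1))
})

test_that("AUC equals the exhaustive concordant-pair count", {
  # 6-sample worked example
  sc <- c(0.9, 0.8, 0.35, 0.4, 0.3, 0.1)
  y <- c("p", "p", "p", "n", "n", "n")
  got <- roc_auc(sc, y, positive = "p")
  expect_equal(got$auc, pair_count_auc(sc, y, "p"))
  expect_equal(got$auc, 8 / 9)  # hand-counted concordant pairs
  # 30 random small instances, including ties
  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("p", "n")
    expect_equal(roc_auc(sc, y, positive = "p")$auc,
                 pair_count_auc(sc, y, "p"), tolerance = 1e-12)
  }
})

test_that("AUC endpoints behave: perfect separation and null scores", {
  y <- rep(c("n", "p"), each = 25)
  expect_equal(roc_auc(c(runif(25, 0, 0.4), runif(25, 0.6, 1)), y,
                       positive = "p")$auc, 1)
  set.seed(13)
  y2 <- rep(c("n", "p"), each = 500)
  null <- roc_auc(rnorm(1000), y2, positive = "p")
  expect_lt(abs(null$auc - 0.5), 0.05)
  expect_false(null$different_from_random)
  expect_error(roc_auc(rnorm(5), rep("p", 5)), "two classes")
})

test_that("DeLong interval matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- rnorm(120)
  y <- rbinom(120, 1, stats::plogis(1.5 * sc))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  got <- roc_auc(sc, y, positive = "1")
  ref <- pROC::ci.auc(pROC::roc(y, sc, quiet = TRUE), method = "delong")
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-9)
  expect_equal(got$ci95, as.numeric(ref[c(1, 3)]), tolerance = 1e-4)
})

test_that("weighted kappa has the textbook fixed points", {
  expect_equal(weighted_kappa(diag(5) * 10)$kappa, 1)
  # independent raters: outer product of marginals -> kappa 0
  p <- c(0.1, 0.2, 0.3, 0.4); q <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(weighted_kappa(outer(p, q) * 200)$kappa, 0,
               tolerance = 1e-9)
  expect_error(weighted_kappa(matrix(1, 2, 3)), "square")
  expect_error(weighted_kappa(matrix(numeric(0), 0, 0)), "square")
})

test_that("kappa CI reproduces the published grading intervals", {
  ref <- reference_confusion_matrices()
  wk <- weighted_kappa(ref$svm_gini, n = attr(ref$svm_gini, "n"))
  expect_equal(100 * wk$ci95, c(57.3, 70.2), tolerance = 0.1)
  expect_equal(wk$agreement, "substantial")
  wk2 <- weighted_kappa(ref$rf_gini, n = attr(ref$rf_gini, "n"))
  expect_equal(100 * wk2$ci95, c(52.3, 66.5), tolerance = 0.2)
})

test_that("confusion matrix accuracy is trace over total", {
  cm <- confusion_matrix(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 3))
  expect_equal(sum(cm$counts), 5)
  expect_equal(cm$accuracy, 4 / 5)
  expect_equal(sum(cm$percent), 100)
})

test_that("task codes group the AREDS categories correctly", {
  lab <- c(1, 2, 3, 4, 2)
  expect_equal(as.character(map_task_labels(lab, "1_234")),
               c("1", "234", "234", "234", "234"))
  expect_equal(levels(map_task_labels(lab, "12_3_4")), c("12", "3", "4"))
  expect_error(map_task_labels(lab, "13_24"), "unknown task")
})

# A tiny in-memory feature set with separable classes; keypoints empty
# so the bag-of-words stage is exercised as a no-op.
toy_feature_set <- function(n_per = 12, seed = 21) {
  set.seed(seed)
  centers <- list(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  X <- do.call(rbind, lapply(centers, function(ctr)
    cbind(rnorm(n_per, ctr[1], 0.4), rnorm(n_per, ctr[2], 0.4))))
  colnames(X) <- c("f1", "f2")
  n <- nrow(X)
  empty_kp <- matrix(numeric(0), 0, 6, dimnames = list(NULL,
    c("laplacian_sign", "orientation", "scale", "strength", "row", "col")))
  structure(list(X = X, groups = rep("HOG", 2),
                 keypoints = rep(list(empty_kp), n),
                 labels = rep(1:4, each = n_per),
                 quality = rep(rep(c("good", "poor"), each = n_per / 2), 4),
                 ids = sprintf("t%02d", 1:n)),
            class = "feature_set")
}

test_that("cross-validation predicts every sample exactly once", {
  fs <- toy_feature_set()
  rep <- kfold_cv(fs, task = "12_34", k = 4, seed = 2, selection = "none",
                  classifier = "rf", use_surf = FALSE)
  expect_false(any(is.na(rep$predicted)))
  expect_equal(length(rep$predicted), 48)
  expect_gt(rep$accuracy, 0.9)      # separable blobs
  expect_gt(rep$auc, 0.95)
  rep2 <- kfold_cv(fs, task = "12_34", k = 4, seed = 2, selection = "none",
                   classifier = "rf", use_surf = FALSE)
  expect_equal(rep$auc, rep2$auc)   # seeded determinism
})

test_that("two-step grading composes its two models consistently", {
  fs <- toy_feature_set(n_per = 12)
  rep <- two_step_grade(fs, k = 3, seed = 5, selection = "none",
                        classifier = "rf", use_surf = FALSE)
  # step-1 {3} or {4} decisions pass through unchanged
  pass <- rep$step1 %in% c("3", "4")
  expect_equal(as.character(rep$predicted[pass]),
               as.character(rep$step1[pass]))
  # step-1 {1&2} decisions are refined into 1 or 2
  expect_true(all(as.character(rep$predicted[!pass]) %in% c("1", "2")))
  # separable toy: the composite recovers the truth
  expect_gt(rep$accuracy, 0.9)
  expect_equal(levels(rep$predicted), as.character(1:4))
})

test_that("the robustness split trains on good and tests on poor only", {
  fs <- toy_feature_set()
  rep <- robustness_split(fs, task = "12_34", seed = 3, selection = "none",
                          classifier = "rf", use_surf = FALSE)
  expect_equal(length(rep$predicted), sum(fs$quality == "poor"))
  expect_gt(rep$auc, 0.9)
  fs_good <- fs; fs_good$quality[] <- "good"
  expect_error(robustness_split(fs_good, task = "12_34"), "empty test")
  fs_poor <- fs; fs_poor$quality[] <- "poor"
  expect_error(robustness_split(fs_poor, task = "12_34"), "empty train")
})
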