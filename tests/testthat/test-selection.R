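test_that("Fisher score matches direct evaluation on toy vectors", {
  # means 1 vs 0, variances 1 and 1 -> (1-0)^2 / (1+1) = 0.5
  expect_equal(fisher_score(c(0, 1, 2, -1, 0, 1),
                            rep(c("a", "b"), each = 3)), 0.5)
  # equal means -> 0
  expect_equal(fisher_score(c(0, 2, 1, 3, -1, 1),
                            rep(c("a", "b"), each = 3)), 0)
  # {0,1,2} vs {5,6,7}: (1-6)^2 / (1+1) = 12.5
  expect_equal(fisher_score(c(0, 1, 2, 5, 6, 7),
                            rep(c("a", "b"), each = 3)), 12.5)
  expect_error(fisher_score(1:4, rep("a", 4)), "two classes")
  expect_warning(out <- fisher_score(rep(1, 6), rep(c("a", "b"), 3)),
                 "zero")
  expect_equal(out, 0)
})

test_that("Fisher score is invariant to affine feature rescaling", {
  set.seed(2)
  x <- rnorm(40)
  y <- rep(c("a", "b"), 20)
  base <- fisher_score(x, y)
  for (a in c(-3, 0.01, 7)) {
    expect_equal(fisher_score(a * x + 5, y), base, tolerance = 1e-12)
  }
})

test_that("the Fisher cap is one-tenth of the training-set size", {
  set.seed(4)
  X <- matrix(rnorm(250 * 40), 250)
  y <- rep(c("a", "b"), length.out = 250)
  X[, 7] <- X[, 7] + ifelse(y == "a", 0, 8)  # one separating feature
  sel <- select_fisher(X, y, seed = 1)
  expect_equal(sel$cap, 25)
  expect_equal(sel$kept[1], 7)
  expect_lte(length(sel$kept), 25)
})

test_that("identical features produce all-zero scores and a warning", {
  X <- matrix(3, 30, 5)
  y <- rep(c("a", "b"), 15)
  expect_warning(sel <- select_fisher(X, y, seed = 1), "zero")
  expect_true(all(sel$scores == 0))
  # tie-break: ranking falls back to ascending index
  expect_equal(sel$kept, seq_along(sel$kept))
})

test_that("Gini importance recovers informative features", {
  set.seed(6)
  runs <- vapply(1:5, function(r) {
    n <- 120
    X <- matrix(rnorm(n * 100), n)
    y <- rep(c("a", "b"), each = n / 2)
    X[, 1:5] <- X[, 1:5] + ifelse(y == "a", 0, 1.5)
    sel <- gini_importance(X, y, n_trees = 500, mtry = 10, seed = r)
    rank10 <- order(-sel$scores)[1:10]
    sum(1:5 %in% rank10)
  }, numeric(1))
  expect_gte(mean(runs == 5), 0.8)  # all 5 in the top 10, almost always
})

test_that("Gini importances are deterministic, non-negative and stable", {
  set.seed(9)
  n <- 100
  X <- matrix(rnorm(n * 200), n)
  y <- rep(c("a", "b"), each = n / 2)
  X[, 1:20] <- X[, 1:20] + ifelse(y == "a", 0, 0.8)
  s1 <- gini_importance(X, y, n_trees = 3000, seed = 5)
  s1b <- gini_importance(X, y, n_trees = 3000, seed = 5)
  expect_identical(s1$scores, s1b$scores)
  expect_true(all(s1$scores >= 0))
  s2 <- gini_importance(X, y, n_trees = 3000, seed = 6)
  rho <- cor(s1$scores, s2$scores, method = "spearman")
  expect_gt(rho, 0.9)
  expect_error(gini_importance(X, rep("a", n)), "two classes")
})

test_that("pure-noise importances show no spuriously dominant feature", {
  hits <- vapply(1:5, function(r) {
    set.seed(100 + r)
    X <- matrix(rnorm(80 * 40), 80)
    y <- rep(c("a", "b"), each = 40)
    sel <- gini_importance(X, y, n_trees = 500, mtry = 5, seed = r)
    max(sel$scores) < 3 * mean(sel$scores)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
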