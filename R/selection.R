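# Feature ranking and selection: Fisher's criterion and random-forest
# mean decrease in Gini.

#' Fisher score of one feature
#'
#' Divergence between two classes projected on a feature axis:
#' `D = (mu_i - mu_j)^2 / (sigma_i^2 + sigma_j^2)`.  For more than two
#' classes the score is the maximum over one-vs-rest pairings.  A zero
#' denominator yields a score of 0 with a warning.
#'
#' @param x numeric feature values, one per sample.
#' @param labels class labels (two or more classes, each with >= 2
#'   samples).
#' @return a non-negative scalar.
#' @export
fisher_score <- function(x, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("fisher_score needs at least two classes")
  if (length(cls) == 2) {
    a <- x[labels == cls[1]]; b <- x[labels == cls[2]]
    if (length(a) < 2 || length(b) < 2)
      stop("each class needs at least two samples")
    den <- stats::var(a) + stats::var(b)
    if (den == 0) {
      warning("zero within-class variance; score set to 0")
      return(0)
    }
    return((mean(a) - mean(b))^2 / den)
  }
  max(vapply(cls, function(k)
    fisher_score(x, ifelse(labels == k, k, "rest")), numeric(1)))
}

# Columnwise Fisher scores (one-vs-rest max for > 2 classes), vectorised.
fisher_scores <- function(X, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  pair <- function(one) {
    in1 <- labels == one
    a <- X[in1, , drop = FALSE]; b <- X[!in1, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums(sweep(a, 2, ma)^2) / (nrow(a) - 1)
    vb <- colSums(sweep(b, 2, mb)^2) / (nrow(b) - 1)
    den <- va + vb
    sc <- (ma - mb)^2 / den
    sc[den == 0] <- 0
    sc
  }
  if (length(cls) == 2) return(pair(cls[1]))
  do.call(pmax, lapply(cls, pair))
}

#' Feature selection by Fisher's criterion
#'
#' Features are ranked by descending Fisher score (ties broken by
#' ascending index).  The cap on the number of retained features is
#' one-tenth of the training-set size; the retained count (1..cap) is
#' the one giving the best SVM accuracy on an inner stratified 80/20
#' validation split of the training data.
#'
#' @param X n x p feature matrix (training samples only).
#' @param labels class labels.
#' @param cap maximum number of features; default `floor(n / 10)`.
#' @param seed seed for the validation split.
#' @return an object of class `selection_result`: list with `scores`,
#'   `method`, `kept` (ordered indices), `cap`, `params`.
#' @export
select_fisher <- function(X, labels, cap = NULL, seed = 1) {
  n <- nrow(X)
  if (is.null(cap)) cap <- floor(n / 10)
  if (cap < 1) stop("fewer than 10 training samples: feature cap < 1")
  scores <- fisher_scores(X, labels)
  if (all(scores == 0))
    warning("all Fisher scores are zero; selection falls back to index order")
  ranked <- order(-scores, seq_along(scores))
  cap <- min(cap, ncol(X))
  y <- factor(labels)
  # inner stratified 80/20 split to tune the retained count
  set.seed(derive_seed(seed, 101))
  val <- unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1, round(0.2 * length(ix))))))
  tr <- setdiff(seq_len(n), val)
  acc <- vapply(seq_len(cap), function(m) {
    cols <- ranked[seq_len(m)]
    Xi <- X[tr, cols, drop = FALSE]
    keep <- apply(Xi, 2, stats::sd) > 0
    if (!any(keep)) return(0)
    fit <- e1071::svm(Xi[, keep, drop = FALSE], y[tr], kernel = "radial")
    mean(predict(fit, X[val, cols[keep], drop = FALSE]) == y[val])
  }, numeric(1))
  m_best <- which.max(acc)
  structure(list(scores = scores, method = "fisher",
                 kept = ranked[seq_len(m_best)], cap = cap,
                 params = list(seed = seed, validation_accuracy = acc)),
            class = "selection_result")
}

#' Feature selection by random-forest Gini importance
#'
#' Mean decrease in Gini impurity from a random forest with 3000 trees
#' and 25 candidate features per split.  Features whose importance
#' stands out from the bulk -- exceeding the mean importance by more
#' than two standard deviations -- are retained (or the `top_k` best,
#' if given).  On high-dimensional screening problems this rule keeps
#' on the order of 1-3% of the features, the regime in which this kind
#' of forest-based selection is reported to operate.
#'
#' @param X n x p feature matrix.
#' @param labels class labels (>= 2 classes).
#' @param n_trees number of trees (default 3000).
#' @param mtry candidate features per split (default 25).
#' @param top_k optional fixed number of features to keep.
#' @param seed seed for the forest.
#' @return a `selection_result` (see [select_fisher()]).
#' @export
gini_importance <- function(X, labels, n_trees = 3000, mtry = 25,
                            top_k = NULL, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("gini_importance needs at least two classes")
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  rf <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                       mtry = min(mtry, ncol(X)), importance = "impurity",
                       num.threads = 1, seed = seed)
  imp <- unname(rf$variable.importance)
  ranked <- order(-imp, seq_along(imp))
  kept <- if (is.null(top_k)) {
    ranked[imp[ranked] > mean(imp) + 2 * stats::sd(imp)]
  } else {
    ranked[seq_len(min(top_k, length(ranked)))]
  }
  if (length(kept) == 0) kept <- ranked[1]  # degenerate flat importances
  structure(list(scores = imp, method = "gini", kept = kept,
                 cap = length(kept),
                 params = list(n_trees = n_trees, mtry = mtry, seed = seed)),
            class = "selection_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, kept %d of %d features\n",
              x$method, length(x$kept), length(x$scores)))
  invisible(x)
}

#' Share of selected features per feature group
#' @param sel a `selection_result`.
#' @param groups per-feature group tags (same length as `sel$scores`).
#' @return a named proportion table over the selected features.
#' @export
selected_group_shares <- function(sel, groups) {
  prop.table(table(groups[sel$kept]))
}
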