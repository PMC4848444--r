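# Evaluation protocol: stratified k-fold CV, ROC/AUC with DeLong CI,
# confusion matrices, linearly weighted kappa, two-step grading and the
# image-quality robustness split.

#' Stratified fold assignment
#'
#' Samples of each class are shuffled and dealt round-robin over `k`
#' folds.  A class with fewer than `k` samples simply leaves some folds
#' without that class (with a warning).
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold id (1..k) per sample.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  y <- factor(labels)
  if (any(table(y) < k))
    warning("some classes have fewer than k samples; folds are uneven")
  folds <- integer(length(y))
  set.seed(derive_seed(seed, 17))
  offset <- 0L
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    folds[ix] <- (seq_along(ix) + offset - 1L) %% k + 1L
    offset <- offset + length(ix)
  }
  folds
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The ROC is traced by thresholding the score at every observed value;
#' the AUC is the trapezoidal area (equivalently the normalised
#' Mann-Whitney count of concordant pairs, ties counting one half).
#' The 95% CI uses DeLong's placement-value variance.  The result is
#' flagged as statistically different from a random classifier when 0.5
#' lies outside the CI.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels binary labels.
#' @param positive the positive class; default the larger level.
#' @return list with `roc` (data.frame fpr/tpr/threshold), `auc`,
#'   `ci95`, `different_from_random`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("roc_auc needs exactly two classes")
  if (is.null(positive)) positive <- levels(y)[2]
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  # DeLong placements
  xs <- scores[pos]; ys <- scores[!pos]
  V10 <- vapply(xs, function(x) mean(ys < x) + 0.5 * mean(ys == x),
                numeric(1))
  V01 <- vapply(ys, function(x) mean(xs > x) + 0.5 * mean(xs == x),
                numeric(1))
  se <- sqrt(stats::var(V10) / length(xs) + stats::var(V01) / length(ys))
  ci <- clip_range(auc + c(-1, 1) * 1.96 * se, 0, 1)
  list(roc = roc, auc = auc, ci95 = ci,
       different_from_random = (0.5 < ci[1] || 0.5 > ci[2]))
}

#' Linearly weighted Cohen's kappa
#'
#' Agreement corrected for chance, with linear weights
#' `w_ij = 1 - |i - j| / (k - 1)` so that near-miss disagreements are
#' penalised less than distant ones.  The 95% CI uses the large-sample
#' variance of Fleiss, Cohen and Everitt.  The verbal scale follows
#' Landis and Koch.
#'
#' @param confusion square matrix of counts or proportions (rows = first
#'   rater / truth, columns = second rater / prediction).
#' @param n total sample count (needed for the CI when `confusion` holds
#'   proportions; defaults to `sum(confusion)`).
#' @return list with `kappa`, `ci95`, `se`, `agreement` (verbal scale).
#' @export
weighted_kappa <- function(confusion, n = NULL) {
  M <- as.matrix(confusion)
  if (nrow(M) != ncol(M) || nrow(M) == 0) stop("confusion must be square")
  if (any(M < 0)) stop("confusion entries must be non-negative")
  if (is.null(n)) n <- sum(M)
  P <- M / sum(M)
  k <- nrow(M)
  w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  p_i <- rowSums(P); q_j <- colSums(P)
  po <- sum(w * P)
  pe <- sum(w * outer(p_i, q_j))
  kap <- (po - pe) / (1 - pe)
  wbar_i <- as.vector(w %*% q_j)     # row-wise expected weights
  wbar_j <- as.vector(t(w) %*% p_i)
  term <- (w - outer(wbar_i, wbar_j, "+") * (1 - kap))^2
  v <- (sum(P * term) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  ci <- clip_range(kap + c(-1, 1) * 1.96 * se, -1, 1)
  scale <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  verbal <- c("slight", "fair", "moderate", "substantial",
              "almost perfect")[findInterval(kap, scale,
                                             rightmost.closed = TRUE)]
  list(kappa = kap, ci95 = ci, se = se,
       agreement = if (kap <= 0) "poor" else verbal)
}

#' Confusion matrix with counts and total-percentage cells
#' @param true,pred label vectors.
#' @param classes class order (default sorted union).
#' @return list with `counts`, `percent` (cells as % of all samples),
#'   `accuracy`.
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(true),
                                                 as.character(pred))))
  cnt <- table(factor(true, classes), factor(pred, classes))
  cnt <- matrix(cnt, length(classes), length(classes),
                dimnames = list(true = classes, predicted = classes))
  list(counts = cnt, percent = 100 * cnt / sum(cnt),
       accuracy = sum(diag(cnt)) / sum(cnt))
}

# ---- task codes ---------------------------------------------------------

.task_groups <- function(task) {
  codes <- list("1_234" = list("1", c("2", "3", "4")),
                "12_34" = list(c("1", "2"), c("3", "4")),
                "12_3_4" = list(c("1", "2"), "3", "4"),
                "1_23_4" = list("1", c("2", "3"), "4"),
                "1_2_3_4" = list("1", "2", "3", "4"))
  if (!task %in% names(codes))
    stop("unknown task code: ", task,
         " (expected one of ", paste(names(codes), collapse = ", "), ")")
  codes[[task]]
}

#' Map AREDS categories onto a classification task
#'
#' Task codes join categories with `&`-style grouping, e.g. `"12_34"`
#' groups {1,2} against {3,4}.  For binary screening tasks the second
#' group (the diseased/severe one) is the positive class.
#'
#' @param labels AREDS categories (1..4).
#' @param task one of `"1_234"`, `"12_34"`, `"12_3_4"`, `"1_23_4"`,
#'   `"1_2_3_4"`.
#' @return factor of group labels (levels in task order).
#' @export
map_task_labels <- function(labels, task) {
  groups <- .task_groups(task)
  nm <- vapply(groups, paste, "", collapse = "")
  out <- rep(NA_character_, length(labels))
  for (i in seq_along(groups))
    out[as.character(labels) %in% groups[[i]]] <- nm[i]
  factor(out, levels = nm)
}

# ---- shared fold machinery ---------------------------------------------

# Fit the per-fold pipeline (vocabulary -> selection -> classifier) on
# the training rows of a feature_set and predict the test rows.
.fit_fold <- function(fs, tr, te, y, config) {
  K <- if (nlevels(y) == 2) config$K_binary else config$K_multi
  kp_train <- fs$keypoints[tr][fs$labels[tr] %in% c(2, 3, 4)]
  vocab <- NULL
  n_kp <- sum(vapply(kp_train, nrow, 0L))
  if (config$use_surf && n_kp >= K)
    vocab <- build_surf_vocabulary(kp_train, K = K,
                                   seed = derive_seed(config$seed, 31))
  fx <- if (is.null(vocab)) fs else append_surf_features(fs, vocab)
  Xtr <- fx$X[tr, , drop = FALSE]
  Xte <- fx$X[te, , drop = FALSE]
  sel <- switch(config$selection,
    fisher = select_fisher(Xtr, y[tr], seed = config$seed),
    gini = gini_importance(Xtr, y[tr], n_trees = config$gini_trees,
                           mtry = config$gini_mtry,
                           seed = derive_seed(config$seed, 41)),
    none = NULL)
  cols <- if (is.null(sel)) seq_len(ncol(Xtr)) else sel$kept
  model <- switch(config$classifier,
    svm = train_svm(Xtr[, cols, drop = FALSE], y[tr],
                    gamma_grid = config$gamma_grid, C_grid = config$C_grid,
                    seed = derive_seed(config$seed, 53),
                    inner_k = config$inner_k),
    rf = train_rf(Xtr[, cols, drop = FALSE], y[tr],
                  seed = derive_seed(config$seed, 59)))
  pred <- predict(model, Xte[, cols, drop = FALSE])
  list(pred = pred, selection = sel, model = model,
       groups = fx$groups)
}

.eval_config <- function(...) {
  config <- list(classifier = "svm", selection = "gini", use_surf = TRUE,
                 K_binary = 100, K_multi = 300, gini_trees = 3000,
                 gini_mtry = 25, gamma_grid = c(0.001, 0.01, 0.1, 1, 10),
                 C_grid = c(1, 10, 50, 100), inner_k = 10, seed = 1)
  mod <- list(...)
  config[names(mod)] <- mod
  stopifnot(config$classifier %in% c("svm", "rf"),
            config$selection %in% c("fisher", "gini", "none"))
  config
}

.make_report <- function(task, y, scores, pred_label, folds, ids,
                         selections = NULL) {
  classes <- levels(y)
  cm <- confusion_matrix(y, factor(pred_label, classes), classes)
  kap <- weighted_kappa(cm$counts)
  rep <- list(task = task, folds = folds, ids = ids,
              true = y, predicted = factor(pred_label, classes),
              scores = scores, confusion = cm, accuracy = cm$accuracy,
              weighted_kappa = kap, selections = selections)
  if (length(classes) == 2) {
    ra <- roc_auc(scores[, 2], y, positive = classes[2])
    rep$roc <- ra$roc
    rep$auc <- ra$auc
    rep$auc_ci95 <- ra$ci95
    rep$different_from_random <- ra$different_from_random
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task %s, n=%d, accuracy %.3f, kappa %.3f\n",
              x$task, length(x$true), x$accuracy, x$weighted_kappa$kappa))
  if (!is.null(x$auc))
    cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc,
                x$auc_ci95[1], x$auc_ci95[2]))
  invisible(x)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Every fold re-fits all data-dependent stages (visual-word vocabulary
#' from AMD-positive training images, feature selection, SVM grid search
#' / forest training) on the training rows only, then predicts the held
#' out rows; every sample is predicted exactly once.
#'
#' @param fs a [featurize_dataset()] result.
#' @param task task code, see [map_task_labels()].
#' @param k folds (default 10).
#' @param seed master seed (folds, vocabulary, selection, classifier).
#' @param ... pipeline settings: `classifier` (`"svm"`/`"rf"`),
#'   `selection` (`"fisher"`/`"gini"`/`"none"`), `use_surf`, `K_binary`,
#'   `K_multi`, `gini_trees`, `gini_mtry`, `gamma_grid`, `C_grid`,
#'   `inner_k`.
#' @return an `eval_report`.
#' @export
kfold_cv <- function(fs, task = "1_234", k = 10, seed = 1, ...) {
  stopifnot(inherits(fs, "feature_set"))
  config <- .eval_config(seed = seed, ...)
  y <- map_task_labels(fs$labels, task)
  folds <- make_folds(y, k = k, seed = seed)
  classes <- levels(y)
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(fs$ids, classes))
  pred <- rep(NA_character_, length(y))
  sels <- list()
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    fit <- .fit_fold(fs, tr, te, y, config)
    scores[te, ] <- fit$pred$scores
    pred[te] <- fit$pred$label
    sels[[f]] <- fit$selection
  }
  .make_report(task, y, scores, pred, folds, fs$ids, sels)
}

#' Two-step grading
#'
#' Step 1 classifies each image into {1&2}, {3} or {4}; step 2
#' re-classifies the predicted {1&2} cases with a binary {1} vs {2}
#' model trained on the category-1/2 training rows.  Both models are
#' fitted inside each cross-validation fold; the composite prediction is
#' a full four-category label.
#'
#' @inheritParams kfold_cv
#' @return an `eval_report` with task `"two_step"`.
#' @export
two_step_grade <- function(fs, k = 10, seed = 1, ...) {
  stopifnot(inherits(fs, "feature_set"))
  config <- .eval_config(seed = seed, ...)
  y3 <- map_task_labels(fs$labels, "12_3_4")
  y4 <- factor(fs$labels, 1:4)
  folds <- make_folds(y4, k = k, seed = seed)
  pred <- rep(NA_character_, length(y4))
  step1_label <- rep(NA_character_, length(y4))
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    step1 <- .fit_fold(fs, tr, te, y3, config)
    p1 <- step1$pred$label
    step1_label[te] <- p1
    pred[te] <- p1
    tr12 <- tr[fs$labels[tr] %in% c(1, 2)]
    te12 <- te[p1 == "12"]
    if (length(te12) > 0) {
      y12 <- factor(fs$labels, 1:2)
      step2 <- .fit_fold(fs, tr12, te12, y12, config)
      pred[te12] <- step2$pred$label
    }
  }
  scores <- matrix(NA_real_, length(y4), 4, dimnames = list(fs$ids, 1:4))
  rep <- .make_report("two_step", y4, scores, pred, folds, fs$ids)
  rep$step1 <- factor(step1_label, c("12", "3", "4"))
  rep
}

#' Image-quality robustness split
#'
#' Trains the pipeline on good-quality images only and tests on the
#' poor-quality images, reporting the same metrics as [kfold_cv()].
#'
#' @inheritParams kfold_cv
#' @return an `eval_report` over the poor-quality test images.
#' @export
robustness_split <- function(fs, task = "1_234", seed = 1, ...) {
  stopifnot(inherits(fs, "feature_set"))
  config <- .eval_config(seed = seed, ...)
  tr <- which(fs$quality == "good")
  te <- which(fs$quality == "poor")
  if (length(tr) == 0) stop("empty train split (no good-quality images)")
  if (length(te) == 0) stop("empty test split (no poor-quality images)")
  y <- map_task_labels(fs$labels, task)
  fit <- .fit_fold(fs, tr, te, y, config)
  scores <- fit$pred$scores
  rownames(scores) <- fs$ids[te]
  .make_report(task, droplevels(y[te]), scores, fit$pred$label,
               rep(1L, length(te)), fs$ids[te], list(fit$selection))
}

# ---- published benchmark matrices --------------------------------------

#' Benchmark four-class grading confusion matrices
#'
#' Published confusion matrices (cells as percentages of all samples,
#' rows = reference grader, columns = prediction) from a 279-image
#' telemedicine AMD grading study, used as worked examples for the
#' weighted-kappa and accuracy computations: the four-class SVM and RF
#' results with Gini-selected features, the two-step variants, and the
#' second human grader on the 176-image overlap subset.
#'
#' @return a named list of 4 x 4 percentage matrices with attributes
#'   `n` (sample count).
#' @export
reference_confusion_matrices <- function() {
  m <- function(v, n) {
    M <- matrix(v, 4, 4, byrow = TRUE,
                dimnames = list(true = 1:4, predicted = 1:4))
    attr(M, "n") <- n
    M
  }
  list(
    svm_gini = m(c(20.1, 6.8, 1.1, 0.4,
                   6.5, 15.8, 4.7, 1.4,
                   1.4, 4.7, 13.3, 3.9,
                   0.7, 0.7, 5.0, 13.6), 279),
    rf_gini = m(c(19.7, 6.5, 1.4, 0.7,
                  7.2, 16.5, 2.9, 1.8,
                  2.2, 5.7, 13.3, 2.1,
                  0.7, 2.2, 5.0, 12.2), 279),
    two_step_svm = m(c(22.6, 4.3, 1.1, 0.3,
                       4.3, 18.3, 4.3, 1.4,
                       1.8, 4.7, 12.2, 4.6,
                       0.7, 1.1, 5.0, 13.3), 279),
    two_step_rf = m(c(21.9, 5.0, 0.7, 0.7,
                      4.7, 19.7, 2.5, 1.4,
                      3.6, 7.1, 10.0, 2.5,
                      1.1, 1.8, 4.7, 12.5), 279),
    grader_b = m(c(31.2, 9.5, 0.6, 0.0,
                   4.5, 19.3, 6.2, 0.6,
                   0.0, 3.4, 7.4, 2.8,
                   0.0, 1.1, 1.1, 13.1), 176))
}
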