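# Classifiers: one-vs-all Gaussian-kernel SVM with grid search, and
# random forest.
#
# The SVM works on precomputed kernel matrices: the pairwise squared
# distances of the z-scored training fold are computed once (BLAS), and
# every (gamma, C) grid candidate reuses them as exp(-gamma * D).  The
# quadratic programme is solved by kernlab on the precomputed kernel;
# per-class probabilities come from a Platt sigmoid fitted to the
# inner-CV decision values of the winning candidate.

# Pairwise squared Euclidean distances between row sets.
.dist2 <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

# Fit one binary C-SVC on a precomputed kernel.  Returns a dense weight
# vector over the training rows plus offset, oriented so that larger
# decision values mean 'pos'.
.ksvm_binary <- function(K, ybin, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), ybin, C = C,
                     type = "C-svc")
  w <- numeric(nrow(K))
  w[unlist(kernlab::alphaindex(m))] <- unlist(kernlab::coef(m))
  b <- kernlab::b(m)
  dec <- as.vector(K %*% w) - b
  if (mean(dec[ybin == "pos"]) < mean(dec[ybin == "neg"])) {
    w <- -w; b <- -b; dec <- -dec
  }
  list(w = w, b = b, dec = dec)
}

# Platt sigmoid: P(pos | d) = plogis(a * d + c), fitted on held-out
# decision values; falls back to a unit-slope sigmoid when the logistic
# fit degenerates (e.g. perfect separation).
.platt_fit <- function(dec, ybin) {
  t <- as.numeric(ybin == "pos")
  fit <- suppressWarnings(tryCatch(
    stats::glm(t ~ dec, family = stats::binomial()),
    error = function(e) NULL))
  if (is.null(fit) || !fit$converged || stats::coef(fit)[2] <= 0) {
    s <- stats::sd(dec); if (!is.finite(s) || s == 0) s <- 1
    return(c(a = 3 / s, c = -3 * stats::median(dec) / s))
  }
  c(a = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]))
}

#' Train a one-vs-all Gaussian-kernel SVM
#'
#' Features are z-scored with training-fold statistics.  The kernel
#' width `gamma` and cost `C` are chosen by grid search over
#' `gamma_grid` x `C_grid` using inner 10-fold cross-validated accuracy.
#' One binary machine is trained per class (one-vs-all); a prediction's
#' hard label is the class whose machine returns the highest decision
#' value (ties to the lowest class id), and Platt-calibrated per-class
#' probabilities -- sigmoids fitted to the inner-CV decision values of
#' the winning grid point -- are available for ROC thresholding.
#' Two-class problems use a single machine and its mirror.
#'
#' @param X n x p feature matrix.
#' @param labels class labels; every class must be present.
#' @param gamma_grid RBF gamma grid (default `c(0.001, 0.01, 0.1, 1, 10)`).
#' @param C_grid cost grid (default `c(1, 10, 50, 100)`).
#' @param seed seed for the inner folds.
#' @param inner_k inner CV folds for the grid search (default 10).
#' @return an object of class `amd_model` (kind `"svm_ova"`).
#' @export
train_svm <- function(X, labels, gamma_grid = c(0.001, 0.01, 0.1, 1, 10),
                      C_grid = c(1, 10, 50, 100), seed = 1, inner_k = 10) {
  y <- factor(labels)
  if (any(table(y) == 0) || nlevels(y) < 2)
    stop("every class must be present in the training data")
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- scale(X, mu, sdv)
  n <- nrow(Z)
  classes <- levels(y)
  eff <- if (nlevels(y) == 2) classes[1] else classes  # machines to fit
  D <- .dist2(Z, Z)
  folds <- make_folds(y, k = min(inner_k, min(table(y))), seed = seed)
  grid <- expand.grid(gamma = gamma_grid, C = C_grid)
  cv_dec <- vector("list", nrow(grid))
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    Kg <- exp(-grid$gamma[g] * D)
    dec <- matrix(NA_real_, n, length(eff), dimnames = list(NULL, eff))
    for (f in unique(folds)) {
      tr <- folds != f
      for (cl in eff) {
        ybin <- factor(ifelse(y[tr] == cl, "pos", "neg"),
                       c("pos", "neg"))
        fit <- .ksvm_binary(Kg[tr, tr, drop = FALSE], ybin, grid$C[g])
        dec[!tr, cl] <- as.vector(Kg[!tr, tr, drop = FALSE] %*% fit$w) -
          fit$b
      }
    }
    full <- if (length(eff) == 1) cbind(dec, -dec) else dec
    pred <- classes[max.col(full, ties.method = "first")]
    cv_acc[g] <- mean(pred == y)
    cv_dec[[g]] <- dec
  }
  best <- which.max(cv_acc)
  Kb <- exp(-grid$gamma[best] * D)
  machines <- lapply(eff, function(cl) {
    ybin <- factor(ifelse(y == cl, "pos", "neg"), c("pos", "neg"))
    fit <- .ksvm_binary(Kb, ybin, grid$C[best])
    platt <- .platt_fit(cv_dec[[best]][, cl], ybin)
    list(w = fit$w, b = fit$b, platt = platt)
  })
  names(machines) <- eff
  structure(list(kind = "svm_ova", machines = machines, classes = classes,
                 gamma = grid$gamma[best], C = grid$C[best],
                 cv_accuracy = max(cv_acc), Z = Z, mu = mu, sd = sdv,
                 features = colnames(X), seed = seed),
            class = "amd_model")
}

#' Train a random-forest classifier
#'
#' Probability forest whose vote fractions serve as class probabilities.
#' Defaults follow the pipeline conventions: 1000 trees for binary and
#' 2500 for multiclass tasks, and `mtry = floor(sqrt(p))` candidate
#' features per split.  Resampling is seed-controlled and indexed by row
#' position, so predictions are reproducible for a fixed training row
#' order.
#'
#' @param X n x p feature matrix.
#' @param labels class labels.
#' @param n_trees number of trees; default 1000 (binary) / 2500
#'   (multiclass).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param seed forest seed.
#' @return an object of class `amd_model` (kind `"rf"`).
#' @export
train_rf <- function(X, labels, n_trees = NULL, mtry = NULL, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("every class must be present in the training data")
  if (is.null(n_trees)) n_trees <- if (nlevels(y) == 2) 1000 else 2500
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(X)))
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  rf <- ranger::ranger(x = X, y = y, num.trees = n_trees, mtry = mtry,
                       probability = TRUE, num.threads = 1, seed = seed)
  structure(list(kind = "rf", forest = rf, classes = levels(y),
                 n_trees = n_trees, mtry = mtry,
                 features = colnames(X), seed = seed),
            class = "amd_model")
}

#' @export
print.amd_model <- function(x, ...) {
  if (x$kind == "svm_ova")
    cat(sprintf("<amd_model svm_ova> classes {%s}, gamma=%g, C=%g\n",
                paste(x$classes, collapse = ","), x$gamma, x$C))
  else
    cat(sprintf("<amd_model rf> classes {%s}, %d trees, mtry=%d\n",
                paste(x$classes, collapse = ","), x$n_trees, x$mtry))
  invisible(x)
}

#' Predict class scores and hard labels
#'
#' @param object an `amd_model`.
#' @param newdata n x p matrix with the training feature order.
#' @param ... unused.
#' @return list with `scores` (n x k matrix of per-class probabilities,
#'   columns named by class) and `label` (hard labels; argmax with ties
#'   broken by the lowest class id).
#' @export
predict.amd_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$features))
    stop(sprintf("feature dimension mismatch: expected %d, received %d",
                 length(object$features), ncol(newdata)))
  classes <- object$classes
  if (object$kind == "svm_ova") {
    Zn <- scale(as.matrix(newdata), object$mu, object$sd)
    K <- exp(-object$gamma * .dist2(Zn, object$Z))
    dec <- vapply(object$machines, function(m)
      as.vector(K %*% m$w) - m$b, numeric(nrow(Zn)))
    dec <- matrix(dec, nrow = nrow(Zn),
                  dimnames = list(NULL, names(object$machines)))
    prob <- vapply(names(object$machines), function(cl) {
      pl <- object$machines[[cl]]$platt
      stats::plogis(pl["a"] * dec[, cl] + pl["c"])
    }, numeric(nrow(Zn)))
    prob <- matrix(prob, nrow = nrow(Zn),
                   dimnames = list(NULL, names(object$machines)))
    if (length(object$machines) == 1) {  # binary: mirror the machine
      dec <- cbind(dec[, 1], -dec[, 1])
      prob <- cbind(prob[, 1], 1 - prob[, 1])
      colnames(dec) <- colnames(prob) <- classes
    }
    return(list(scores = prob[, classes, drop = FALSE],
                label = classes[max.col(dec[, classes, drop = FALSE],
                                        ties.method = "first")]))
  }
  colnames(newdata) <- object$features
  p <- predict(object$forest, data = newdata, num.threads = 1)$predictions
  p <- p[, classes, drop = FALSE]
  list(scores = p,
       label = classes[max.col(p, ties.method = "first")])
}
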