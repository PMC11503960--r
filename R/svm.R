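# RBF soft-margin support vector machine with a small deterministic SMO
# solver, plus leave-one-out cross-validation. Cohorts here are tiny
# (n ~ 18), so a dependency-free dual solver is both adequate and keeps the
# model fully serializable.

#' Train the seizure-freedom SVM
#'
#' Radial basis function kernel, cost `C = 1`, `gamma = 1/n_factors`
#' (0.25 for the four FR factors) on normalized features. Features are
#' z-scored (default) by training-set statistics; normalization is refit
#' inside every cross-validation fold. Deterministic given the training
#' set.
#'
#' @param features numeric matrix (n x p), or list of `metric_vector`s.
#' @param labels logical (TRUE = seizure free) or character vector with
#'   values `"seizure_free"` / `"not_seizure_free"`.
#' @param config a [run_config()].
#' @return object of class `fr_svm`: normalization, kernel parameters,
#'   support coefficients, bias, training metadata.
#' @export
train_svm <- function(features, labels, config = run_config()) {
  X <- as_feature_matrix(features)
  y <- as_pm1(labels)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 training samples")
  if (length(unique(y)) < 2) stop("training labels are single-class")
  norm <- fit_normalization(X, config$svm_normalization)
  Z <- apply_normalization(X, norm)
  gamma <- svm_gamma(Z, config$svm_gamma_rule)
  K <- rbf_kernel(Z, Z, gamma)
  sol <- smo_solve(K, y, C = config$svm_C)
  structure(list(
    normalization = norm, gamma = gamma, C = config$svm_C,
    X = Z, y = y, alpha = sol$alpha, b = sol$b,
    n = n, label_counts = table(y)
  ), class = "fr_svm")
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "metric_vector"))) {
    features <- do.call(rbind, lapply(features, as_feature_row))
  }
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  X
}

as_pm1 <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  if (is.character(labels)) {
    stopifnot(all(labels %in% c("seizure_free", "not_seizure_free")))
    return(ifelse(labels == "seizure_free", 1, -1))
  }
  stopifnot(all(labels %in% c(-1, 1)))
  as.numeric(labels)
}

fit_normalization <- function(X, method) {
  if (method == "zscore") {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(method = "zscore", center = mu, scale = sd)
  } else {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    list(method = "minmax", center = lo, scale = rng)
  }
}

apply_normalization <- function(X, norm) {
  sweep(sweep(X, 2, norm$center, "-"), 2, norm$scale, "/")
}

svm_gamma <- function(Z, rule) {
  if (rule == "n_factors") return(1 / ncol(Z))
  # auto-scale heuristic: kernel width from the median pairwise distance
  d <- stats::dist(Z)
  sigma <- stats::median(d[d > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  1 / (2 * sigma^2)
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Deterministic simplified SMO (Platt) on the dual problem. The second
# index is chosen as the maximiser of |E_i - E_j| (ties -> lowest index),
# so the solver is reproducible.
smo_solve <- function(K, y, C, tol = 1e-4, eps = 1e-8, max_passes = 500) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  decision <- function() as.numeric(K %*% (alpha * y)) + b
  for (pass in seq_len(max_passes)) {
    changed <- 0L
    E <- decision() - y
    for (i in seq_len(n)) {
      Ei <- E[i]
      r <- y[i] * Ei
      if ((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0)) {
        cand <- abs(E - Ei)
        cand[i] <- -Inf
        j <- which.max(cand)
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (H - L < eps) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= -eps) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < eps) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
        else if (aj > 0 && aj < C) b2
        else (b1 + b2) / 2
        alpha[i] <- ai; alpha[j] <- aj
        E <- decision() - y
        changed <- changed + 1L
      }
    }
    if (changed == 0L) break
  }
  list(alpha = alpha, b = b)
}

#' Decision value and label for a metric vector
#'
#' @param model a trained `fr_svm`.
#' @param x a `metric_vector`, a numeric factor vector, or a matrix of rows.
#' @return `predict_label()`: `"seizure_free"` / `"not_seizure_free"` per
#'   row; `decision_value()`: the signed decision function.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "fr_svm"))
  if (inherits(x, "metric_vector")) x <- as_feature_row(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("input features must be finite")
  Z <- apply_normalization(as_feature_matrix(x), model$normalization)
  Kx <- rbf_kernel(Z, model$X, model$gamma)
  as.numeric(Kx %*% (model$alpha * model$y)) + model$b
}

#' @rdname decision_value
#' @export
predict_label <- function(model, x) {
  if (is.function(model)) return(model(x))   # test stubs / custom rules
  ifelse(decision_value(model, x) > 0, "seizure_free", "not_seizure_free")
}

#' Leave-one-out cross-validated accuracy
#'
#' n folds, each refitting the normalization and the SVM on the remaining
#' samples; accuracy is the fraction of held-out samples labelled
#' correctly (1 - k-fold loss).
#'
#' @inheritParams train_svm
#' @return scalar in \[0, 1\].
#' @export
loocv_accuracy <- function(features, labels, config = run_config()) {
  X <- as_feature_matrix(features)
  y <- as_pm1(labels)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  correct <- vapply(seq_len(n), function(i) {
    m <- train_svm(X[-i, , drop = FALSE], y[-i], config)
    lab <- predict_label(m, X[i, , drop = FALSE])
    (lab == "seizure_free") == (y[i] == 1)
  }, logical(1))
  mean(correct)
}
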