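#' Predict class probabilities
#'
#' Generic estimator contract shared by every base learner and by the
#' ensemble itself: an object implementing `predict_proba` returns one row
#' per input row with columns `p_negative`, `p_positive` summing to 1.
#'
#' @param object A fitted model.
#' @param X Numeric feature matrix.
#' @param ... Passed to methods.
#' @return Numeric matrix `n x 2` with columns `p_negative`, `p_positive`.
#' @export
predict_proba <- function(object, X, ...) UseMethod("predict_proba")

#' Base-learner specification
#'
#' The three base-classifier families with their grid-search hyperparameter
#' spaces: RBF-kernel SVM (`C` in \{0.1, 1, 10\}), L2-regularized logistic
#' regression (`C` in \{1, 10, 100\}), and CART with Gini impurity
#' (`max_depth` in \{unlimited, 5, 10\}, `min_samples_leaf` in \{1, 3, 5\}).
#'
#' @param family One of `"svm_rbf"`, `"logreg_l2"`, `"cart"`.
#' @param grid Optional `data.frame` overriding the default grid (one row per
#'   candidate). Useful for cutting cost in smoke runs.
#' @return An object of class `elas_learner_spec`.
#' @export
learner_spec <- function(family = c("svm_rbf", "logreg_l2", "cart"),
                         grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("hyperparameter grid must be non-empty")
  structure(list(family = family, grid = grid), class = "elas_learner_spec")
}

default_grid <- function(family) {
  switch(family,
    svm_rbf = data.frame(C = c(0.1, 1, 10)),
    logreg_l2 = data.frame(C = c(1, 10, 100)),
    cart = expand.grid(max_depth = c(NA, 5, 10),
                       min_samples_leaf = c(1, 3, 5))
  )
}

#' @export
print.elas_learner_spec <- function(x, ...) {
  cat(sprintf("<elas_learner_spec> %s, %d-point grid\n", x$family, nrow(x$grid)))
  invisible(x)
}

#' Grid-search hyperparameter tuning by stratified cross-validation
#'
#' Evaluates every grid point of a learner spec by stratified k-fold
#' cross-validation and returns the point maximizing the mean held-out
#' metric. Ties break towards the earlier grid row, so a degenerate grid is
#' resolved deterministically.
#'
#' @param spec An [learner_spec()].
#' @param X Numeric feature matrix.
#' @param y Binary labels (both classes present, each with at least
#'   `n_folds` members).
#' @param n_folds Folds for the tuning CV (default 5).
#' @param metric Scorer `function(scores, labels)`; default [auroc].
#' @param seed Integer seed controlling fold assignment.
#' @return List with `params` (named list, the chosen grid row), `cv_score`,
#'   and `grid_scores` (mean metric per grid row).
#' @export
tune <- function(spec, X, y, n_folds = 5, metric = auroc, seed = 1L) {
  stopifnot(inherits(spec, "elas_learner_spec"))
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))
  folds <- make_internal_folds(y, n_folds, seed)
  grid_scores <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- as.list(spec$grid[g, , drop = FALSE])
    fold_scores <- vapply(folds, function(fold) {
      fit <- fit_base(spec, params, X[fold$pool, , drop = FALSE], y[fold$pool],
                      seed = seed)
      p <- predict_proba(fit, X[fold$internal_val, , drop = FALSE])
      metric(p[, "p_positive"], y[fold$internal_val])
    }, numeric(1))
    mean(fold_scores)
  }, numeric(1))
  best <- which.max(grid_scores) # first maximum = earliest grid row
  list(params = as.list(spec$grid[best, , drop = FALSE]),
       cv_score = grid_scores[best],
       grid_scores = grid_scores)
}

#' Fit one base classifier
#'
#' Dispatches to the family backend: the in-package RBF-kernel SVM (dual QP
#' plus Platt-calibrated probabilities), ridge logistic regression via
#' glmnet with `lambda = 1/(C * n)` so `C` keeps its usual inverse-
#' regularization meaning, or the in-package Gini CART. All backends are
#' deterministic given the data; `seed` is fixed around the fit so any
#' backend-internal randomness is pinned.
#'
#' @param spec An [learner_spec()].
#' @param params Named list of hyperparameters (a row of the grid).
#' @param X Numeric feature matrix.
#' @param y Binary labels with both classes present.
#' @param seed Integer seed (default 0).
#' @return A fitted classifier implementing [predict_proba()].
#' @export
fit_base <- function(spec, params, X, y, seed = 0L) {
  stopifnot(inherits(spec, "elas_learner_spec"))
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))
  if (length(unique(y)) < 2) stop("fit_base requires both classes in y")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  switch(spec$family,
    svm_rbf = fit_svm_rbf(X, y, C = params$C),
    logreg_l2 = fit_logreg_l2(X, y, C = params$C),
    cart = fit_cart(X, y, max_depth = params$max_depth,
                    min_samples_leaf = params$min_samples_leaf)
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# ridge-penalized logistic regression; coefficients extracted so prediction
# needs no glmnet object (and the model serializes as plain numbers)
fit_logreg_l2 <- function(X, y, C = 1) {
  X <- as.matrix(X)
  padded <- ncol(X) < 2
  if (padded) X <- cbind(X, .pad = 0) # glmnet requires >= 2 columns
  lambda <- 1 / (C * nrow(X))
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) {
      # tiny balanced seeds routinely have < 8 per class; expected here
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- as.numeric(fit$beta)
  if (padded) beta <- beta[1]
  structure(
    list(family = "logreg_l2", intercept = as.numeric(fit$a0), beta = beta,
         C = C),
    class = c("elas_logreg_l2", "elas_base")
  )
}

#' @export
predict_proba.elas_logreg_l2 <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$beta)) stop("logreg: feature count mismatch")
  eta <- object$intercept + as.numeric(X %*% object$beta)
  proba_matrix(stats::plogis(eta))
}

#' @export
predict.elas_base <- function(object, newdata, threshold = 0.5, ...) {
  as.integer(predict_proba(object, newdata)[, "p_positive"] >= threshold)
}
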