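# RBF-kernel C-SVC solved as the standard dual quadratic program, with
# Platt sigmoid calibration so the classifier emits class probabilities.
# Kept as a plain-list model so ensembles serialize to JSON.

rbf_kernel <- function(a, b, gamma) {
  exp(-gamma * cross_dist2(a, b))
}

# sklearn-style "scale" gamma: 1 / (n_features * population variance of X)
gamma_scale <- function(X) {
  v <- mean((X - mean(X))^2)
  if (v <= 0) v <- 1
  1 / (ncol(X) * v)
}

fit_svm_rbf <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))
  if (length(unique(y)) < 2) stop("svm_rbf requires both classes in y")
  if (is.null(gamma)) gamma <- gamma_scale(X)
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Q <- tcrossprod(yy) * K

  sol <- NULL
  ridge <- 1e-8
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(
        Dmat = Q + diag(ridge, n),
        dvec = rep(1, n),
        Amat = cbind(yy, diag(n), -diag(n)),
        bvec = c(0, rep(0, n), rep(-C, n)),
        meq = 1
      ),
      error = function(e) NULL
    )
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("SVM dual QP failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), C)

  tol <- 1e-7 * max(C, 1)
  sv <- alpha > tol
  if (!any(sv)) sv <- alpha == max(alpha)
  f_no_b <- as.numeric(K %*% (alpha * yy))
  free <- sv & alpha < C - tol
  b <- if (any(free)) {
    mean(yy[free] - f_no_b[free])
  } else {
    mean(yy[sv] - f_no_b[sv])
  }

  platt <- platt_fit(f_no_b + b, y)
  structure(
    list(
      family = "svm_rbf",
      sv = X[sv, , drop = FALSE],
      coef = (alpha * yy)[sv],
      b = b, gamma = gamma, C = C,
      platt_a = platt[1], platt_b = platt[2]
    ),
    class = c("elas_svm_rbf", "elas_base")
  )
}

svm_decision <- function(object, X) {
  as.numeric(rbf_kernel(as.matrix(X), object$sv, object$gamma) %*% object$coef) +
    object$b
}

#' @export
predict_proba.elas_svm_rbf <- function(object, X, ...) {
  f <- svm_decision(object, X)
  p <- 1 / (1 + exp(object$platt_a * f + object$platt_b))
  proba_matrix(p)
}

# Platt (2000) sigmoid fit on decision values, with the prior-smoothed
# targets t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2); deterministic BFGS.
platt_fit <- function(f, y) {
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  t <- ifelse(y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # log(1 + exp(z)) computed stably
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  start <- c(-1, log((n_neg + 1) / (n_pos + 1)))
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  fit$par
}

proba_matrix <- function(p_pos) {
  p_pos <- pmin(pmax(p_pos, 0), 1)
  m <- cbind(1 - p_pos, p_pos)
  colnames(m) <- c("p_negative", "p_positive")
  m
}
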