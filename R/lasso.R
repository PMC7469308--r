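# Internal: column standardization with population (1/n) variance, the
# convention of the classical penalized-regression solvers.  Zero-variance
# columns are flagged inactive and kept at coefficient zero.
standardize_columns <- function(x) {
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  active <- scale > 1e-12
  xs <- sweep(x, 2, center)
  xs[, active] <- sweep(xs[, active, drop = FALSE], 2, scale[active], "/")
  xs[, !active] <- 0
  list(x = xs, center = center, scale = scale, active = active)
}

mean_loglik <- function(eta, y) {
  mean(y * eta - log1p(exp(eta)))
}

binomial_deviance <- function(p, y) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit an L1-penalized logistic regression at a fixed penalty
#'
#' Maximizes the mean penalized log-likelihood
#' \deqn{\frac1n\sum_i\{y_i\eta_i-\log(1+e^{\eta_i})\}-\lambda\sum_j|\beta_j|,}
#' \eqn{\eta_i=\beta_0+\sum_j\beta_j x_{ij}}, by coordinate descent with an
#' IRLS outer loop.  The intercept is unpenalized; covariates are
#' standardized to unit variance internally and coefficients are returned
#' on the original scale (the standardized-scale coefficients, on which the
#' penalty acts, are kept in `$beta_std`).
#'
#' @param design A `design_matrix` from [encode_design()] (or a list with
#'   elements `x` and `y`).
#' @param lam Penalty \eqn{\lambda \ge 0}.
#' @param tol Convergence tolerance on the linear predictor (default 1e-9).
#' @param max_iter Outer-iteration cap (default 200).
#' @return An object of class `penalized_lr_fit`: intercept `beta0` and
#'   coefficients `beta` on the original scale, `beta_std`, `lambda`,
#'   achieved penalized `objective`, KKT residual `kkt`, `converged` flag.
#' @seealso [lambda_path()], [kkt_residuals()]
#' @export
fit_penalized_lr <- function(design, lam, tol = 1e-9, max_iter = 200) {
  x <- design$x; y <- as.numeric(design$y)
  stopifnot(is.matrix(x), length(y) == nrow(x), lam >= 0)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")

  std <- standardize_columns(x)
  p0 <- mean(y)
  init <- rep(0, ncol(x))
  res <- cd_logistic_lasso(std$x, y, lam, qlogis(p0), init, std$active,
                           tol, as.integer(max_iter))
  if (!res$converged)
    warning("fit_penalized_lr did not converge in ", max_iter,
            " iterations (lambda=", signif(lam, 4), ")")
  beta_std <- as.numeric(res$beta)
  beta <- ifelse(std$active, beta_std / ifelse(std$active, std$scale, 1), 0)
  beta0 <- res$beta0 - sum(beta * std$center)
  names(beta) <- names(beta_std) <- colnames(x)

  eta <- res$beta0 + drop(std$x %*% beta_std)
  fit <- structure(list(
    beta0 = beta0, beta = beta, beta_std = beta_std,
    lambda = lam,
    objective = mean_loglik(eta, y) - lam * sum(abs(beta_std)),
    converged = res$converged, iterations = res$iterations,
    column_characteristic = design$column_characteristic,
    std = std[c("center", "scale", "active")]),
    class = "penalized_lr_fit")
  fit$kkt <- kkt_residuals(fit, design)
  fit
}

#' KKT residuals of a penalized logistic fit
#'
#' On the standardized scale, with score
#' \eqn{g_j = \frac1n\sum_i \tilde x_{ij}(y_i - p_i)}, stationarity of the
#' penalized objective requires \eqn{|g_j| \le \lambda} when
#' \eqn{\beta_j = 0} and \eqn{g_j = \lambda\,\mathrm{sign}(\beta_j)}
#' otherwise.  Returns the per-column violation, zero at an exact optimum.
#'
#' @param fit A `penalized_lr_fit`.
#' @param design The `design_matrix` it was fitted to.
#' @return Numeric vector of non-negative residuals, one per column.
#' @export
kkt_residuals <- function(fit, design) {
  x <- design$x; y <- as.numeric(design$y)
  std <- standardize_columns(x)
  eta <- fit$beta0 + drop(x %*% fit$beta)
  p <- plogis(eta)
  g <- colMeans(std$x * (y - p))
  lam <- fit$lambda
  res <- ifelse(abs(fit$beta_std) > 1e-10,
                abs(g - lam * sign(fit$beta_std)),
                pmax(0, abs(g) - lam))
  res[!std$active] <- 0
  res
}

#' @export
print.penalized_lr_fit <- function(x, ...) {
  nz <- sum(abs(x$beta) > 1e-10)
  cat(sprintf("<penalized_lr_fit> lambda=%.5g, %d/%d nonzero coefficients%s\n",
              x$lambda, nz, length(x$beta),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.penalized_lr_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

# fit a warm-started coefficient path over a decreasing lambda sequence;
# x,y raw (standardization internal).  Returns original- and
# standardized-scale coefficients per lambda.
fit_lambda_sequence <- function(x, y, lambdas, tol = 1e-7, max_iter = 100) {
  std <- standardize_columns(x)
  m <- ncol(x)
  beta_std <- rep(0, m)
  beta0_std <- qlogis(mean(y))
  betas <- matrix(0, m, length(lambdas),
                  dimnames = list(colnames(x), NULL))
  betas_std <- betas
  beta0s <- numeric(length(lambdas))
  for (k in seq_along(lambdas)) {
    res <- cd_logistic_lasso(std$x, y, lambdas[k], beta0_std, beta_std,
                             std$active, tol, as.integer(max_iter))
    beta_std <- as.numeric(res$beta)
    beta0_std <- res$beta0
    betas_std[, k] <- beta_std
    b <- ifelse(std$active, beta_std / ifelse(std$active, std$scale, 1), 0)
    betas[, k] <- b
    beta0s[k] <- beta0_std - sum(b * std$center)
  }
  list(lambdas = lambdas, beta0 = beta0s, beta = betas,
       beta_std = betas_std)
}

stratified_folds <- function(y, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated penalty path for the L1-penalized logistic model
#'
#' Computes \eqn{\lambda_{max}} (the smallest penalty with an all-zero
#' slope vector, \eqn{\max_j |\frac1n\sum_i \tilde x_{ij}(y_i-\bar y)|} on
#' standardized columns), lays a log-spaced grid down to
#' `lambda_min_ratio * lambda_max`, fits the warm-started coefficient path
#' on the full data, and estimates the held-out binomial deviance by
#' stratified k-fold cross-validation.  `lambda_min` minimizes the mean CV
#' deviance; `lambda_1se` is the largest penalty within one standard error
#' of that minimum.
#'
#' @param design A `design_matrix`.
#' @param folds Number of CV folds (default 10, stratified by outcome).
#' @param n_lambda Grid size (default 100).
#' @param seed Integer seed for the fold assignment.
#' @param lambda_min_ratio Ratio of the smallest to largest grid penalty
#'   (default 0.01).
#' @param tol,max_iter Passed to the coordinate-descent solver.
#' @return An object of class `lambda_path`: `lambdas` (decreasing),
#'   `cv_mean`, `cv_se`, `lambda_min`, `lambda_1se`, full-data coefficient
#'   path `beta` (columns per lambda) and `beta0`, and the indices
#'   `index_min`, `index_1se`.
#' @export
lambda_path <- function(design, folds = 10, n_lambda = 100, seed,
                        lambda_min_ratio = 0.01, tol = 1e-7,
                        max_iter = 100) {
  x <- design$x; y <- as.numeric(design$y)
  n <- nrow(x)
  if (missing(seed)) stop("seed is required")
  if (n < folds) stop("fewer observations than folds")
  if (min(table(y)) < folds)
    stop("a class has fewer members than folds; stratified folding degenerate")

  std <- standardize_columns(x)
  lambda_max <- max(abs(colMeans(std$x * (y - mean(y)))))
  lambdas <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                     length.out = n_lambda))

  full <- fit_lambda_sequence(x, y, lambdas, tol, max_iter)

  fold <- stratified_folds(y, folds, seed)
  dev <- matrix(NA_real_, n_lambda, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("degenerate fold ", f)
    pathf <- fit_lambda_sequence(x[tr, , drop = FALSE], y[tr], lambdas,
                                 tol, max_iter)
    eta <- sweep(x[!tr, , drop = FALSE] %*% pathf$beta, 2, pathf$beta0, "+")
    p <- plogis(eta)
    dev[, f] <- vapply(seq_len(n_lambda),
                       function(k) binomial_deviance(p[, k], y[!tr]),
                       numeric(1))
  }
  cv_mean <- rowMeans(dev)
  cv_se <- apply(dev, 1, sd) / sqrt(folds)
  i_min <- which.min(cv_mean)
  ok <- which(cv_mean <= cv_mean[i_min] + cv_se[i_min])
  i_1se <- min(ok)  # lambdas are decreasing: first index = largest lambda

  structure(list(lambdas = lambdas, cv_mean = cv_mean, cv_se = cv_se,
                 lambda_min = lambdas[i_min], lambda_1se = lambdas[i_1se],
                 index_min = i_min, index_1se = i_1se,
                 beta = full$beta, beta0 = full$beta0,
                 beta_std = full$beta_std,
                 column_characteristic = design$column_characteristic,
                 folds = folds, seed = seed),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("<lambda_path> %d lambdas in [%.4g, %.4g]; lambda_min=%.4g, lambda_1se=%.4g\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              x$lambda_min, x$lambda_1se))
  invisible(x)
}

#' @export
plot.lambda_path <- function(x, ...) {
  ll <- log(x$lambdas)
  plot(ll, x$cv_mean, type = "b", pch = 20,
       xlab = expression(log(lambda)), ylab = "CV binomial deviance", ...)
  arrows(ll, x$cv_mean - x$cv_se, ll, x$cv_mean + x$cv_se,
         length = 0.02, angle = 90, code = 3, col = "grey60")
  abline(v = log(c(x$lambda_min, x$lambda_1se)), lty = c(3, 2))
  invisible(x)
}

#' Coefficients of a penalty path at a chosen penalty
#'
#' @param object A `lambda_path`.
#' @param s Either `"lambda_1se"` (default), `"lambda_min"`, or a numeric
#'   penalty (snapped to the nearest grid point).
#' @param ... Unused.
#' @return Named vector: intercept followed by original-scale coefficients.
#' @export
coef.lambda_path <- function(object, s = "lambda_1se", ...) {
  k <- if (identical(s, "lambda_1se")) object$index_1se
       else if (identical(s, "lambda_min")) object$index_min
       else which.min(abs(object$lambdas - as.numeric(s)))
  c("(Intercept)" = object$beta0[k], object$beta[, k])
}
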