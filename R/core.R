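#' Standardize a regression design
#'
#' Centers each predictor column and scales it to unit Euclidean norm
#' (correlation form), and centers the response. All canonical-form
#' computations in the package assume this convention; unit column norms
#' make the eigenvalues of \eqn{X'X} comparable across sample sizes.
#'
#' @param X_raw Numeric matrix (n x p) of predictors, n > p, full column rank.
#' @param y_raw Numeric response vector of length n.
#' @return An object of class `"regdata"`: a list with elements `X`
#'   (standardized design), `y` (centered response), `n`, `p`,
#'   `standardized`, `column_centers`, `column_scales`, `y_center`.
#'   The stored centers and scales allow exact recovery of the raw data
#'   and back-transformation of coefficients (see [back_transform()]).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, 0.5, -1) + rnorm(20)
#' d <- standardize_design(X, y)
#' colSums(d$X)          # ~ 0
#' colSums(d$X^2)        # ~ 1
#' @export
standardize_design <- function(X_raw, y_raw) {
  X_raw <- as.matrix(X_raw)
  y_raw <- as.numeric(y_raw)
  n <- nrow(X_raw)
  p <- ncol(X_raw)
  if (anyNA(X_raw) || anyNA(y_raw)) stop("missing values in design or response")
  if (length(y_raw) != n) stop("length of y does not match rows of X")
  if (n <= p) stop("underdetermined: n must exceed p")
  centers <- colMeans(X_raw)
  Xc <- sweep(X_raw, 2, centers, "-")
  scales <- sqrt(colSums(Xc^2))
  if (any(scales < 1e-12)) stop("zero-variance column in design")
  X <- sweep(Xc, 2, scales, "/")
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[p] <= 1e-10 * sv[1]) stop("singular design")
  y_center <- mean(y_raw)
  structure(list(
    X = X, y = y_raw - y_center, n = n, p = p,
    standardized = TRUE,
    column_centers = centers, column_scales = scales, y_center = y_center
  ), class = "regdata")
}

#' Canonical decomposition of a standardized design
#'
#' Rotates the model by the eigenvectors of \eqn{X'X} so the design becomes
#' column-orthogonal: \eqn{Z = XT}, \eqn{Z'Z = \Lambda =
#' diag(\lambda_1, \dots, \lambda_p)} with descending eigenvalues. Every
#' closed-form MSE expression and shrinkage operator in the package works in
#' these coordinates. A deterministic sign convention (first nonzero entry of
#' each eigenvector positive) keeps the rotation reproducible across
#' platforms.
#'
#' @param data A `"regdata"` object from [standardize_design()].
#' @return An object of class `"canonical_form"`: list with `lambdas`
#'   (descending eigenvalues), `T` (p x p orthogonal eigenvector matrix),
#'   `Z` (n x p rotated design).
#' @export
canonical_decompose <- function(data) {
  stopifnot(inherits(data, "regdata"))
  XtX <- crossprod(data$X)
  eg <- eigen(XtX, symmetric = TRUE)
  lambdas <- eg$values
  if (any(lambdas <= 1e-12)) stop("effectively singular design")
  Tm <- eg$vectors
  for (j in seq_len(ncol(Tm))) {
    nz <- which(abs(Tm[, j]) > 1e-12)[1]
    if (Tm[nz, j] < 0) Tm[, j] <- -Tm[, j]
  }
  structure(list(lambdas = lambdas, T = Tm, Z = data$X %*% Tm),
            class = "canonical_form")
}

#' Huber M-estimation control parameters
#'
#' @param tuning_c Huber tuning constant c; the default 1.345 gives 95\%
#'   efficiency at the Gaussian model.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on `max|delta alpha| / (1 + max|alpha|)`.
#' @param scale_rule `"mad_iterated"` re-estimates the robust scale
#'   (MAD/0.6745 of current residuals) at every IRLS iteration;
#'   `"mad_fixed"` freezes the scale at the initial OLS residuals.
#' @return A list of class `"huber_control"`.
#' @export
huber_control <- function(tuning_c = 1.345, max_iter = 100L, tol = 1e-8,
                          scale_rule = c("mad_iterated", "mad_fixed")) {
  scale_rule <- match.arg(scale_rule)
  stopifnot(tuning_c > 0, max_iter >= 1, tol > 0)
  structure(list(tuning_c = tuning_c, max_iter = as.integer(max_iter),
                 tol = tol, scale_rule = scale_rule),
            class = "huber_control")
}

#' Huber psi function and its derivative
#'
#' \eqn{\psi(u) = u} for \eqn{|u| \le c}, \eqn{c\,sign(u)} otherwise.
#'
#' @param u Numeric vector of standardized residuals.
#' @param c Tuning constant.
#' @return Numeric vector.
#' @export
huber_psi <- function(u, c = 1.345) pmax(-c, pmin(c, u))

#' @rdname huber_psi
#' @export
huber_psi_prime <- function(u, c = 1.345) as.numeric(abs(u) <= c)

# robust scale: MAD about zero of residuals, normalized for Gaussian
# consistency; falls back to mean absolute residual * 1.2533 when the MAD
# degenerates (more than half the residuals exactly zero)
.robust_scale <- function(e) {
  s <- stats::median(abs(e)) / 0.6745
  if (s < 1e-12) {
    s <- mean(abs(e)) * 1.2533
    attr(s, "mad_fallback") <- TRUE
  }
  s
}

.new_fit <- function(estimator, alpha_hat, cf, k = 0, d = 0,
                     scale_s = NULL, weights = NULL, converged = TRUE,
                     iterations = 0L, scale_fallback = FALSE) {
  structure(list(
    estimator = estimator,
    alpha_hat = as.numeric(alpha_hat),
    beta_hat = as.numeric(cf$T %*% alpha_hat),
    k = k, d = d,
    scale_s = scale_s, weights = weights,
    converged = converged, iterations = as.integer(iterations),
    scale_fallback = scale_fallback
  ), class = "rtmme_fit")
}

#' Ordinary least squares in canonical coordinates
#'
#' \eqn{\hat\alpha = \Lambda^{-1} Z'y}; equivalent to the normal-equations
#' solution on the standardized design.
#'
#' @param cf A `"canonical_form"` object.
#' @param y Centered response vector.
#' @return An `"rtmme_fit"` with `estimator = "OLS"`.
#' @export
fit_ols <- function(cf, y) {
  stopifnot(inherits(cf, "canonical_form"), length(y) == nrow(cf$Z))
  alpha <- drop(crossprod(cf$Z, y)) / cf$lambdas
  .new_fit("OLS", alpha, cf)
}

#' Huber M-estimation by iteratively reweighted least squares
#'
#' Solves the M-estimating equations \eqn{\sum_i \psi(e_i/s) z_i = 0} in
#' canonical coordinates, with the Huber psi and a robust residual scale.
#' IRLS starts from the OLS fit; each iteration solves an exact weighted
#' least-squares problem with weights \eqn{w_i = \min(1, c s / |e_i|)} and
#' (under the default scale rule) re-estimates s as MAD/0.6745 of the
#' current residuals.
#'
#' @inheritParams fit_ols
#' @param control A [huber_control()] list.
#' @return An `"rtmme_fit"` with `estimator = "M"`, the robust scale
#'   `scale_s`, the final IRLS `weights` (in (0, 1]), a `converged` flag,
#'   the iteration count, and `eq_norm`, the max-abs residual of the
#'   estimating equations at the solution.
#' @export
fit_huber_m <- function(cf, y, control = huber_control()) {
  stopifnot(inherits(cf, "canonical_form"), length(y) == nrow(cf$Z))
  Z <- cf$Z
  c0 <- control$tuning_c
  alpha <- drop(crossprod(Z, y)) / cf$lambdas
  e <- y - drop(Z %*% alpha)
  s <- .robust_scale(e)
  scale_fallback <- isTRUE(attr(s, "mad_fallback"))
  s_fixed <- as.numeric(s)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, length(y))
  for (iter in seq_len(control$max_iter)) {
    u <- e / as.numeric(s)
    w <- ifelse(abs(u) <= c0, 1, c0 / abs(u))
    # exact WLS step: solve (Z' W Z) a = Z' W y
    ZtW <- t(Z * w)
    alpha_new <- solve(ZtW %*% Z, ZtW %*% y)
    delta <- max(abs(alpha_new - alpha)) / (1 + max(abs(alpha_new)))
    alpha <- drop(alpha_new)
    e <- y - drop(Z %*% alpha)
    if (control$scale_rule == "mad_iterated") {
      s <- .robust_scale(e)
      scale_fallback <- scale_fallback || isTRUE(attr(s, "mad_fallback"))
    } else {
      s <- s_fixed
    }
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }
  s <- as.numeric(s)
  u <- e / s
  w <- ifelse(abs(u) <= c0, 1, c0 / abs(u))
  fit <- .new_fit("M", alpha, cf, scale_s = s, weights = w,
                  converged = converged, iterations = iter,
                  scale_fallback = scale_fallback)
  fit$eq_norm <- max(abs(drop(crossprod(cf$Z, huber_psi(u, c0)))))
  fit$residuals <- e
  fit
}

#' Generic two-parameter shrinkage operator
#'
#' Applies \eqn{R_{kd} = \Lambda(\Lambda + k(1+d)I)^{-1}} componentwise:
#' \eqn{\alpha_i \mapsto \lambda_i / (\lambda_i + k(1+d)) \, \alpha_i}.
#' With the OLS coefficients as base this realizes the ridge (d = 0) and
#' modified ridge-type (MRT) estimators; with the M coefficients it realizes
#' ridge-M (d = 0) and the RTMME.
#'
#' @param alpha_base Canonical coefficient vector to shrink.
#' @param lambdas Positive eigenvalues of X'X.
#' @param k Ridge biasing parameter, k >= 0.
#' @param d Second biasing parameter, d >= 0.
#' @return Shrunk coefficient vector.
#' @export
apply_shrinkage <- function(alpha_base, lambdas, k, d = 0) {
  if (k < 0 || d < 0) stop("invalid biasing parameter: k and d must be >= 0")
  stopifnot(all(lambdas > 0), length(alpha_base) == length(lambdas))
  lambdas / (lambdas + k * (1 + d)) * alpha_base
}

#' Estimators recognized by [fit_named()]
#' @export
ESTIMATORS <- c("OLS", "M", "RIDGE", "RIDGE_M", "MRT", "RTMME")

#' Fit any of the six estimators by name
#'
#' Dispatches to [fit_ols()], [fit_huber_m()], and [apply_shrinkage()].
#' The estimator family forms a reduction lattice: `RIDGE(k = 0)` is OLS,
#' `MRT(k, 0)` is `RIDGE(k)`, `MRT(k, d)` is `RIDGE(k(1+d))`,
#' `RTMME(0, 0)` is the M-estimator, and `RTMME(k, 0)` is `RIDGE_M(k)`.
#'
#' @param estimator One of `"OLS"`, `"M"`, `"RIDGE"`, `"RIDGE_M"`,
#'   `"MRT"`, `"RTMME"`.
#' @param data A `"regdata"` object, or a `"canonical_form"` may be supplied
#'   via `cf` to reuse a decomposition.
#' @param k,d Biasing parameters; `k` is ignored for OLS/M and `d` for
#'   RIDGE/RIDGE_M.
#' @param control A [huber_control()] list (M-based estimators only).
#' @param cf Optional precomputed `"canonical_form"` for `data`.
#' @param y Optional centered response (required when `cf` is given in place
#'   of `data`).
#' @return An `"rtmme_fit"`.
#' @export
fit_named <- function(estimator, data = NULL, k = 0, d = 0,
                      control = huber_control(), cf = NULL, y = NULL) {
  estimator <- match.arg(estimator, ESTIMATORS)
  if (is.null(cf)) {
    stopifnot(inherits(data, "regdata"))
    cf <- canonical_decompose(data)
    y <- data$y
  }
  if (estimator %in% c("OLS", "RIDGE")) d <- 0
  if (estimator %in% c("OLS", "M")) { k <- 0; d <- 0 }
  base <- if (estimator %in% c("OLS", "RIDGE", "MRT")) {
    fit_ols(cf, y)
  } else {
    fit_huber_m(cf, y, control)
  }
  if (estimator %in% c("OLS", "M")) return(base)
  alpha <- apply_shrinkage(base$alpha_hat, cf$lambdas, k, d)
  fit <- .new_fit(estimator, alpha, cf, k = k, d = d,
                  scale_s = base$scale_s, weights = base$weights,
                  converged = base$converged, iterations = base$iterations,
                  scale_fallback = isTRUE(base$scale_fallback))
  fit$eq_norm <- base$eq_norm
  fit
}

#' Residual variance estimate from the OLS fit
#'
#' RSS/(n - p) in canonical coordinates; feeds the theoretical MSE
#' expressions and theorem checkers when applied to real data.
#'
#' @inheritParams fit_ols
#' @return Scalar, >= 0.
#' @export
estimate_sigma2 <- function(cf, y) {
  fit <- fit_ols(cf, y)
  e <- y - drop(cf$Z %*% fit$alpha_hat)
  sum(e^2) / (length(y) - length(cf$lambdas))
}

#' Back-transform coefficients to the raw data scale
#'
#' Undoes the centering/unit-norm scaling of [standardize_design()] and
#' returns slopes on the original predictor scale with the implied
#' intercept.
#'
#' @param fit An `"rtmme_fit"` (its `beta_hat` is on the standardized scale).
#' @param data The `"regdata"` the fit was computed from.
#' @return List with `coefficients` (length p, raw scale) and `intercept`.
#' @export
back_transform <- function(fit, data) {
  stopifnot(inherits(fit, "rtmme_fit"), inherits(data, "regdata"))
  if (!isTRUE(data$standardized)) stop("missing standardization metadata")
  coef_raw <- fit$beta_hat / data$column_scales
  intercept <- data$y_center - sum(coef_raw * data$column_centers)
  list(coefficients = coef_raw, intercept = intercept)
}

#' @export
print.rtmme_fit <- function(x, ...) {
  cat(sprintf("%s fit (k = %g, d = %g)\n", x$estimator, x$k, x$d))
  cat("canonical coefficients:", format(x$alpha_hat, digits = 4), "\n")
  cat("standardized-scale coefficients:", format(x$beta_hat, digits = 4), "\n")
  if (!is.null(x$scale_s)) {
    cat(sprintf("robust scale s = %.4g, converged = %s (%d iterations)\n",
                x$scale_s, x$converged, x$iterations))
  }
  invisible(x)
}
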