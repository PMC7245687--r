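#' Monte Carlo scenario specification
#'
#' One cell of the simulation study design: sample size, predictor count,
#' collinearity level, error scale, contamination scheme, biasing-parameter
#' grids, replication count, and seed. Defaults for the grids follow the
#' study design: k in {0.3, 0.7, 0.9}, d in {0.2, 0.5, 0.8}, 2000
#' replications.
#'
#' @param n Observations, n > p + 1 (and n >= 10 when outliers are injected).
#' @param p Predictors.
#' @param rho Collinearity parameter in [0, 1); pairs of generated raw
#'   predictor columns have population correlation rho^2.
#' @param sigma Error standard deviation, > 0.
#' @param n_outliers 0, 1 or 2 contaminated responses per replication.
#' @param k_grid,d_grid Biasing-parameter grids.
#' @param reps Replications.
#' @param seed Integer seed; the scenario is fully reproducible from it.
#' @param redraw_design If TRUE the design matrix is redrawn every
#'   replication; the default holds X fixed across replications.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n, p, rho, sigma, n_outliers = 0,
                          k_grid = c(0.3, 0.7, 0.9),
                          d_grid = c(0.2, 0.5, 0.8),
                          reps = 2000L, seed = 1L, redraw_design = FALSE) {
  stopifnot(n > p + 1, rho >= 0, rho < 1, sigma > 0,
            n_outliers %in% 0:2, reps >= 1,
            length(k_grid) >= 1, length(d_grid) >= 1)
  if (n_outliers > 0 && n < 10) {
    stop("outlier injection targets observations 5 and 10; need n >= 10")
  }
  structure(list(n = as.integer(n), p = as.integer(p), rho = rho,
                 sigma = sigma, n_outliers = as.integer(n_outliers),
                 k_grid = k_grid, d_grid = d_grid,
                 reps = as.integer(reps), seed = as.integer(seed),
                 redraw_design = isTRUE(redraw_design)),
            class = "scenario_spec")
}

#' Generate a correlated design matrix
#'
#' Draws an n x (p+1) standard-normal array z and sets
#' \eqn{x_{ij} = (1-\rho^2)^{1/2} z_{ij} + \rho z_{i,p+1}}, so every pair
#' of raw columns has population correlation \eqn{\rho^2} and unit
#' population variance. By default the columns are then centered and scaled
#' to unit Euclidean norm (the package's standardization convention).
#'
#' @param n,p Dimensions.
#' @param rho Collinearity parameter in [0, 1).
#' @param standardize If FALSE return the raw draws.
#' @return n x p numeric matrix.
#' @export
generate_design <- function(n, p, rho, standardize = TRUE) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  z <- matrix(stats::rnorm(n * (p + 1)), n, p + 1)
  X <- sqrt(1 - rho^2) * z[, seq_len(p), drop = FALSE] + rho * z[, p + 1]
  if (!standardize) return(X)
  Xc <- sweep(X, 2, colMeans(X), "-")
  sweep(Xc, 2, sqrt(colSums(Xc^2)), "/")
}

#' True coefficients for the simulation study
#'
#' The unit-norm eigenvector of X'X belonging to its largest eigenvalue
#' (first nonzero entry positive), so that \eqn{\beta'\beta = 1} — the
#' standard coefficient choice in shrinkage simulation designs.
#'
#' @param X Full-rank design matrix.
#' @return Length-p unit vector.
#' @export
true_coefficients <- function(X) {
  eg <- eigen(crossprod(X), symmetric = TRUE)
  if (length(eg$values) > 1 &&
      abs(eg$values[1] - eg$values[2]) < 1e-10 * abs(eg$values[1])) {
    warning("tied largest eigenvalue; using stable-sorted first eigenvector")
  }
  b <- eg$vectors[, 1]
  nz <- which(abs(b) > 1e-12)[1]
  if (b[nz] < 0) b <- -b
  b / sqrt(sum(b^2))
}

#' Simulate a response vector
#'
#' \eqn{y_i = \sum_j \beta_j x_{ij} + \varepsilon_i} with iid Gaussian
#' errors (the intercept is taken as zero; the fitting pipeline centers
#' responses, so a nonzero intercept would be absorbed anyway).
#'
#' @param X Design matrix.
#' @param beta Coefficient vector.
#' @param sigma Error standard deviation, >= 0.
#' @return Length-n response.
#' @export
simulate_response <- function(X, beta, sigma) {
  stopifnot(ncol(X) == length(beta), sigma >= 0)
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, sigma)
}

#' Inject y-direction outliers
#'
#' Case 0 leaves y untouched; case 1 shifts the tenth observation by
#' +20 sigma; case 2 shifts the fifth by +20 sigma and the tenth by
#' -20 sigma.
#'
#' @param y Response vector, length >= 10 when outliers are requested.
#' @param n_outliers 0, 1 or 2.
#' @param sigma Error standard deviation used to size the shift.
#' @return Modified response vector.
#' @export
inject_outliers <- function(y, n_outliers, sigma) {
  stopifnot(n_outliers %in% 0:2)
  if (n_outliers == 0) return(y)
  if (length(y) < 10) stop("need at least 10 observations to inject outliers")
  if (n_outliers >= 1) y[10] <- y[10] + if (n_outliers == 1) 20 * sigma else -20 * sigma
  if (n_outliers == 2) y[5] <- y[5] + 20 * sigma
  y
}

#' Empirical MSE over replications
#'
#' \eqn{(1/R)\sum_j (\hat\alpha_j - \alpha)'(\hat\alpha_j - \alpha)} with
#' its Monte Carlo standard error.
#'
#' @param alpha_hats reps x p matrix of estimates (one row per replication).
#' @param true_alpha Length-p truth.
#' @return List with `mse` and `mc_se`.
#' @export
estimate_empirical_mse <- function(alpha_hats, true_alpha) {
  alpha_hats <- as.matrix(alpha_hats)
  stopifnot(ncol(alpha_hats) == length(true_alpha))
  se <- rowSums(sweep(alpha_hats, 2, true_alpha, "-")^2)
  list(mse = mean(se),
       mc_se = if (length(se) > 1) stats::sd(se) / sqrt(length(se)) else NA_real_)
}

#' Run one Monte Carlo scenario
#'
#' Generates the design (once, unless `redraw_design`), sets the true
#' coefficients via [true_coefficients()], and per replication simulates a
#' response, injects outliers, centers y, fits OLS and the Huber M base
#' estimators once, and applies the shrinkage operator at every (k, d) grid
#' cell to produce the ridge, ridge-M, MRT, and RTMME estimates. Aggregates
#' empirical MSEs on the canonical coefficient scale.
#'
#' @param spec A [scenario_spec()].
#' @param control A [huber_control()].
#' @return List of class `"scenario_result"`: `spec`, `true_alpha`,
#'   `mse_table` (long data.frame with columns estimator, k, d, mse,
#'   mc_se), `n_nonconverged`, `max_eq_norm`.
#' @export
run_scenario <- function(spec, control = huber_control()) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p; reps <- spec$reps
  X <- generate_design(n, p, spec$rho)
  beta <- true_coefficients(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  cells <- expand.grid(k = spec$k_grid, d = spec$d_grid,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)

  err_ols <- matrix(NA_real_, reps, 1)
  err_m <- matrix(NA_real_, reps, 1)
  err_ridge <- matrix(NA_real_, reps, n_cells)
  err_ridgem <- matrix(NA_real_, reps, n_cells)
  err_mrt <- matrix(NA_real_, reps, n_cells)
  err_rtmme <- matrix(NA_real_, reps, n_cells)

  n_nonconv <- 0L
  max_eq <- 0
  cf <- NULL; alpha_true <- NULL
  sq_err <- function(a, truth) sum((a - truth)^2)

  for (r in seq_len(reps)) {
    if (spec$redraw_design || r == 1L) {
      if (spec$redraw_design && r > 1L) {
        X <- generate_design(n, p, spec$rho)
        beta <- true_coefficients(X)
      }
      d0 <- structure(list(X = X, y = NULL, n = n, p = p,
                           standardized = TRUE,
                           column_centers = rep(0, p),
                           column_scales = rep(1, p), y_center = 0),
                      class = "regdata")
      cf <- canonical_decompose(d0)
      alpha_true <- drop(crossprod(cf$T, beta))
    }
    y <- simulate_response(X, beta, spec$sigma)
    y <- inject_outliers(y, spec$n_outliers, spec$sigma)
    y <- y - mean(y)
    a_ols <- fit_ols(cf, y)$alpha_hat
    mfit <- fit_huber_m(cf, y, control)
    if (!mfit$converged) n_nonconv <- n_nonconv + 1L
    max_eq <- max(max_eq, mfit$eq_norm)
    a_m <- mfit$alpha_hat
    err_ols[r, 1] <- sq_err(a_ols, alpha_true)
    err_m[r, 1] <- sq_err(a_m, alpha_true)
    for (j in seq_len(n_cells)) {
      k <- cells$k[j]; d <- cells$d[j]
      err_ridge[r, j] <- sq_err(
        apply_shrinkage(a_ols, cf$lambdas, k, 0), alpha_true)
      err_ridgem[r, j] <- sq_err(
        apply_shrinkage(a_m, cf$lambdas, k, 0), alpha_true)
      err_mrt[r, j] <- sq_err(
        apply_shrinkage(a_ols, cf$lambdas, k, d), alpha_true)
      err_rtmme[r, j] <- sq_err(
        apply_shrinkage(a_m, cf$lambdas, k, d), alpha_true)
    }
  }
  if (n_nonconv > 0.01 * reps) {
    warning(sprintf("IRLS failed to converge in %d of %d replications",
                    n_nonconv, reps))
  }

  summarize <- function(errs, j) {
    e <- errs[, j]
    c(mse = mean(e), mc_se = stats::sd(e) / sqrt(length(e)))
  }
  rows <- lapply(seq_len(n_cells), function(j) {
    k <- cells$k[j]; d <- cells$d[j]
    est <- rbind(OLS = summarize(err_ols, 1), M = summarize(err_m, 1),
                 RIDGE = summarize(err_ridge, j),
                 RIDGE_M = summarize(err_ridgem, j),
                 MRT = summarize(err_mrt, j),
                 RTMME = summarize(err_rtmme, j))
    data.frame(estimator = rownames(est), k = k, d = d,
               mse = est[, "mse"], mc_se = est[, "mc_se"],
               row.names = NULL)
  })
  structure(list(spec = spec, true_alpha = alpha_true,
                 mse_table = do.call(rbind, rows),
                 n_nonconverged = n_nonconv, max_eq_norm = max_eq),
            class = "scenario_result")
}

#' Run a grid of scenarios
#'
#' Concatenates the per-scenario MSE tables into one long-format table
#' annotated with the scenario factors; deterministic given the per-scenario
#' seeds.
#'
#' @param specs List of [scenario_spec()] objects.
#' @param control A [huber_control()].
#' @return data.frame with columns n, p, rho, sigma, outliers, seed, k, d,
#'   estimator, mse, mc_se.
#' @export
run_grid <- function(specs, control = huber_control()) {
  out <- lapply(specs, function(sp) {
    res <- run_scenario(sp, control)
    cbind(data.frame(n = sp$n, p = sp$p, rho = sp$rho, sigma = sp$sigma,
                     outliers = sp$n_outliers, seed = sp$seed),
          res$mse_table)
  })
  do.call(rbind, out)
}

#' @export
print.scenario_result <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "scenario: n = %d, p = %d, rho = %.2f, sigma = %g, %d outlier(s), %d reps\n",
    sp$n, sp$p, sp$rho, sp$sigma, sp$n_outliers, sp$reps))
  print(x$mse_table, digits = 4)
  invisible(x)
}
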