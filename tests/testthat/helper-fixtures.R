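# synthetic regression problems and random theoretical settings used
# throughout the suite; all randomness is controlled by the caller's seed

make_regdata <- function(n = 30, p = 3, rho = 0.5, sigma = 1, beta = NULL) {
  Z <- matrix(rnorm(n * (p + 1)), n, p + 1)
  X <- sqrt(1 - rho^2) * Z[, seq_len(p), drop = FALSE] + rho * Z[, p + 1]
  if (is.null(beta)) beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  standardize_design(X, y)
}

random_setting <- function(p = 4, k = NULL, d = NULL) {
  if (is.null(k)) k <- runif(1, 0.01, 5)
  if (is.null(d)) d <- runif(1, 0, 2)
  theoretical_setting(
    lambdas = sort(exp(rnorm(p, 0, 1)), decreasing = TRUE),
    alpha = rnorm(p),
    sigma2 = runif(1, 0.1, 4),
    omega_diag = runif(p, 0.01, 2),
    k = k, d = d
  )
}

# two-column instance with exactly equal canonical M coefficients: for any
# standardized p = 2 design the eigenvectors of X'X sit at 45 degrees, so a
# response along the first predictor has canonical coefficients (a, a); the
# error pattern is orthogonal to {1, x1, x2} and stays inside the linear
# region of psi, so the M fit equals OLS exactly. The per-component d_i
# then all equal the initial d and the harmonic-mean d is positive (no
# Step-4 fallback).
make_no_fallback_data <- function(a = 1, eps = 0.5) {
  u <- c(1, 1, 1, 1, -1, -1, -1, -1)
  v <- c(1, -1, 1, -1, 1, -1, 1, -1)
  e <- c(1, 1, -1, -1, 1, 1, -1, -1)
  standardize_design(cbind(u, u + v), a * u + eps * e)
}

# regdata wrapper around a bare design matrix (already mean-centered
# columns), bypassing re-standardization; used where a test controls the
# design directly
wrap_design <- function(X) {
  structure(list(X = X, y = NULL, n = nrow(X), p = ncol(X),
                 standardized = TRUE,
                 column_centers = rep(0, ncol(X)),
                 column_scales = rep(1, ncol(X)), y_center = 0),
            class = "regdata")
}
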