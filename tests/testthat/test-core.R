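test_that("standardization centers, unit-norms, and round-trips", {
  X <- cbind(c(1, 2, 3), c(4, 0, 2))
  y <- c(0, 0, 0)
  d <- standardize_design(X, y)
  expect_equal(d$X[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(d$y, c(0, 0, 0))

  set.seed(101)
  d2 <- make_regdata(n = 25, p = 4)
  expect_true(max(abs(colMeans(d2$X))) < 1e-10)
  expect_true(max(abs(colSums(d2$X^2) - 1)) < 1e-10)
  expect_lt(abs(mean(d2$y)), 1e-10)
  # invert via stored centers/scales
  X_back <- sweep(sweep(d2$X, 2, d2$column_scales, "*"),
                  2, d2$column_centers, "+")
  d3 <- standardize_design(X_back, d2$y + d2$y_center)
  expect_equal(d3$X, d2$X, tolerance = 1e-10)
})

test_that("standardization rejects degenerate designs", {
  expect_error(standardize_design(cbind(1:5, rep(2, 5)), rnorm(5)),
               "zero-variance")
  expect_error(standardize_design(cbind(1:5, 2 * (1:5)), rnorm(5)),
               "singular")
  expect_error(standardize_design(matrix(rnorm(6), 2, 3), rnorm(2)),
               "underdetermined")
})

test_that("canonical decomposition is exact and deterministically signed", {
  # orthogonal mean-zero columns: X'X = diag(4, 1), so T = I
  X <- cbind(c(1, -1, 1, -1), 0.5 * c(1, 1, -1, -1))
  cf <- canonical_decompose(wrap_design(X))
  expect_equal(cf$lambdas, c(4, 1), tolerance = 1e-12)
  expect_equal(cf$T, diag(2), tolerance = 1e-12)

  set.seed(102)
  d <- make_regdata(n = 20, p = 3)
  cf <- canonical_decompose(d)
  expect_lt(max(abs(crossprod(cf$T) - diag(3))), 1e-10)
  expect_lt(max(abs(crossprod(cf$Z) - diag(cf$lambdas))), 1e-8)
  expect_true(all(diff(cf$lambdas) <= 0))
  # sign convention: first nonzero entry of each eigenvector positive
  firsts <- apply(cf$T, 2, function(v) v[which(abs(v) > 1e-12)[1]])
  expect_true(all(firsts > 0))
})

test_that("canonical OLS matches the direct normal-equations solve", {
  set.seed(103)
  for (rep in 1:10) {
    d <- make_regdata(n = 25, p = 3, rho = runif(1, 0, 0.95))
    cf <- canonical_decompose(d)
    fit <- fit_ols(cf, d$y)
    beta_direct <- solve(crossprod(d$X), crossprod(d$X, d$y))
    expect_equal(fit$beta_hat, drop(beta_direct), tolerance = 1e-10)
    expect_equal(fit$beta_hat, drop(cf$T %*% fit$alpha_hat),
                 tolerance = 1e-12)
  }
  # noiseless response is recovered exactly
  set.seed(104)
  d <- make_regdata(n = 20, p = 3, sigma = 0, beta = c(1, -2, 0.5))
  cf <- canonical_decompose(d)
  alpha_true <- drop(crossprod(cf$Z, d$y)) / cf$lambdas
  expect_equal(fit_ols(cf, d$y)$alpha_hat, alpha_true, tolerance = 1e-10)
})

test_that("Huber IRLS solves the M-estimating equations", {
  set.seed(105)
  d <- make_regdata(n = 40, p = 3, rho = 0.8)
  cf <- canonical_decompose(d)
  m <- fit_huber_m(cf, d$y)
  expect_true(m$converged)
  expect_lt(m$eq_norm, 1e-6)
  expect_true(all(m$weights > 0 & m$weights <= 1))
  # weight formula at the solution
  u <- m$residuals / m$scale_s
  expect_equal(m$weights, pmin(1, 1.345 / abs(u)), tolerance = 1e-12)
})

test_that("Huber M agrees with an independent IRLS implementation", {
  skip_if_not_installed("MASS")
  set.seed(106)
  for (rep in 1:5) {
    d <- make_regdata(n = 35, p = 3, rho = 0.7)
    y <- d$y
    y[sample(35, 2)] <- y[sample(35, 2)] + 15  # contaminate
    cf <- canonical_decompose(d)
    m <- fit_huber_m(cf, y, huber_control(scale_rule = "mad_iterated"))
    r <- suppressWarnings(MASS::rlm(cf$Z, y, psi = MASS::psi.huber,
                                    k = 1.345, maxit = 200, acc = 1e-9,
                                    intercept = FALSE))
    expect_equal(m$alpha_hat, unname(coef(r)), tolerance = 1e-5)
  }
})

test_that("M fit equals OLS when no residual leaves the linear region", {
  set.seed(107)
  d <- make_regdata(n = 30, p = 2, sigma = 0.01, beta = c(1, 1))
  cf <- canonical_decompose(d)
  # huge tuning constant: psi is the identity everywhere
  m <- fit_huber_m(cf, d$y, huber_control(tuning_c = 1e6))
  o <- fit_ols(cf, d$y)
  expect_lt(max(abs(m$alpha_hat - o$alpha_hat)), 1e-6)
})

test_that("M fit resists a gross y-outlier better than OLS", {
  set.seed(108)
  beta <- c(2, -1, 0.5)
  d <- make_regdata(n = 20, p = 3, sigma = 0.5, beta = beta)
  cf <- canonical_decompose(d)
  alpha_clean <- fit_ols(cf, d$y)$alpha_hat
  y_bad <- d$y
  y_bad[7] <- y_bad[7] + 50
  y_bad <- y_bad - mean(y_bad)
  m <- fit_huber_m(cf, y_bad)
  o <- fit_ols(cf, y_bad)
  expect_lt(sum((m$alpha_hat - alpha_clean)^2),
            sum((o$alpha_hat - alpha_clean)^2))
})

test_that("shrinkage operator identities and monotonicity hold", {
  lambdas <- c(2, 1, 0.2)
  a <- c(1.5, -2, 0.7)
  expect_identical(apply_shrinkage(a, lambdas, 0, 0.7), a)
  expect_equal(apply_shrinkage(2, 2, 1, 1), 1)
  # (k, d) and (k(1+d), 0) coincide
  expect_identical(apply_shrinkage(a, lambdas, 0.4, 0.5),
                   apply_shrinkage(a, lambdas, 0.6, 0))
  expect_error(apply_shrinkage(a, lambdas, -1, 0), "invalid biasing")
  # componentwise |alpha| non-increasing in k and d, -> 0 as k -> Inf
  ks <- c(0, 0.1, 1, 10, 1e6)
  mags <- sapply(ks, function(k) abs(apply_shrinkage(a, lambdas, k, 0.3)))
  expect_true(all(diff(t(mags)) <= 1e-14))
  expect_lt(max(mags[, length(ks)]), 1e-5)
})

test_that("the estimator family reduces along its lattice", {
  set.seed(109)
  for (rep in 1:20) {
    d <- make_regdata(n = 30, p = 4, rho = runif(1, 0, 0.99))
    k <- runif(1, 0.05, 3)
    dd <- runif(1, 0.05, 1)
    f <- function(e, k = 0, dpar = 0) fit_named(e, d, k = k, d = dpar)$alpha_hat
    expect_equal(f("RIDGE", 0), f("OLS"), tolerance = 1e-10)
    expect_equal(f("MRT", k, 0), f("RIDGE", k), tolerance = 1e-10)
    expect_equal(f("MRT", k, dd), f("RIDGE", k * (1 + dd)), tolerance = 1e-10)
    expect_equal(f("RTMME", 0, 0), f("M"), tolerance = 1e-10)
    expect_equal(f("RTMME", k, 0), f("RIDGE_M", k), tolerance = 1e-10)
  }
})

test_that("sigma2 estimate matches the hat-matrix computation", {
  set.seed(110)
  d <- make_regdata(n = 25, p = 3)
  cf <- canonical_decompose(d)
  H <- d$X %*% solve(crossprod(d$X)) %*% t(d$X)
  expected <- drop(t(d$y) %*% (diag(25) - H) %*% d$y) / (25 - 3)
  expect_equal(estimate_sigma2(cf, d$y), expected, tolerance = 1e-10)
  # noiseless case
  y0 <- drop(cf$Z %*% c(1, 2, 3))
  expect_lt(estimate_sigma2(cf, y0), 1e-12)
})

test_that("back-transformed OLS coefficients match lm on the raw data", {
  set.seed(111)
  X_raw <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  y_raw <- drop(X_raw %*% c(1, -0.5, 2)) + 7 + rnorm(20)
  d <- standardize_design(X_raw, y_raw)
  fit <- fit_named("OLS", d)
  bt <- back_transform(fit, d)
  ref <- lm(y_raw ~ X_raw)
  expect_equal(bt$coefficients, unname(coef(ref)[-1]), tolerance = 1e-8)
  expect_equal(bt$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  # fitted values reproduced from the raw-scale coefficients
  expect_equal(drop(X_raw %*% bt$coefficients) + bt$intercept,
               unname(fitted(ref)), tolerance = 1e-8)
})

test_that("fitted values are invariant to orthogonal rotation of X", {
  set.seed(112)
  d <- make_regdata(n = 25, p = 3, rho = 0.9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  cf1 <- canonical_decompose(wrap_design(d$X))
  cf2 <- canonical_decompose(wrap_design(d$X %*% Q))
  for (est in c("OLS", "M", "RTMME")) {
    f1 <- fit_named(est, k = 0.5, d = 0.3, cf = cf1, y = d$y)
    f2 <- fit_named(est, k = 0.5, d = 0.3, cf = cf2, y = d$y)
    expect_equal(drop(cf1$Z %*% f1$alpha_hat),
                 drop(cf2$Z %*% f2$alpha_hat), tolerance = 1e-8)
  }
})
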