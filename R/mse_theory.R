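#' Theoretical setting for canonical MSE comparison
#'
#' Bundles the quantities the closed-form MSE expressions depend on: the
#' eigenvalues of X'X, the true canonical coefficients, the error variance,
#' the diagonal of the asymptotic covariance of the canonical M-estimator,
#' and the biasing parameters.
#'
#' @param lambdas Positive eigenvalues, length p.
#' @param alpha True canonical coefficients, length p.
#' @param sigma2 Error variance, >= 0.
#' @param omega_diag Diagonal of Omega = Cov(alpha_M), length p, >= 0.
#' @param k,d Biasing parameters, >= 0.
#' @return List of class `"theoretical_setting"`.
#' @export
theoretical_setting <- function(lambdas, alpha, sigma2, omega_diag,
                                k = 0, d = 0) {
  p <- length(lambdas)
  stopifnot(length(alpha) == p, length(omega_diag) == p,
            all(lambdas > 0), sigma2 >= 0, all(omega_diag >= 0),
            k >= 0, d >= 0)
  structure(list(lambdas = lambdas, alpha = alpha, sigma2 = sigma2,
                 omega_diag = omega_diag, k = k, d = d),
            class = "theoretical_setting")
}

#' Closed-form canonical MSE of the six estimators
#'
#' Scalar mean squared error \eqn{E[(\hat\alpha - \alpha)'(\hat\alpha -
#' \alpha)]} of each estimator in canonical coordinates:
#' \deqn{OLS: \sigma^2 \sum 1/\lambda_i}
#' \deqn{M: \sum \Omega_{ii}}
#' \deqn{RIDGE: \sum [\sigma^2\lambda_i + k^2\alpha_i^2]/(\lambda_i+k)^2}
#' \deqn{RIDGE\_M: \sum [\lambda_i^2\Omega_{ii} + k^2\alpha_i^2]/(\lambda_i+k)^2}
#' \deqn{MRT: \sum [\sigma^2\lambda_i + k^2(1+d)^2\alpha_i^2]/(\lambda_i+k(1+d))^2}
#' \deqn{RTMME: \sum [\lambda_i^2\Omega_{ii} + k^2(1+d)^2\alpha_i^2]/(\lambda_i+k(1+d))^2}
#'
#' @param estimator One of [ESTIMATORS].
#' @param s A [theoretical_setting()].
#' @return Scalar MSE, >= 0.
#' @export
theoretical_mse <- function(estimator, s) {
  estimator <- match.arg(estimator, ESTIMATORS)
  l <- s$lambdas; a2 <- s$alpha^2; om <- s$omega_diag
  k <- s$k; kd <- s$k * (1 + s$d)
  switch(estimator,
    OLS     = s$sigma2 * sum(1 / l),
    M       = sum(om),
    RIDGE   = sum((s$sigma2 * l + k^2 * a2) / (l + k)^2),
    RIDGE_M = sum((l^2 * om + k^2 * a2) / (l + k)^2),
    MRT     = sum((s$sigma2 * l + kd^2 * a2) / (l + kd)^2),
    RTMME   = sum((l^2 * om + kd^2 * a2) / (l + kd)^2)
  )
}

#' MSE difference: RTMME minus MRT
#'
#' \eqn{\Delta_1 = \sum \lambda_i(\lambda_i\Omega_{ii} - \sigma^2) /
#' (\lambda_i + k(1+d))^2}. Negative for every k > 0 whenever
#' \eqn{\Omega_{ii} < \sigma^2/\lambda_i} componentwise.
#'
#' @param s A [theoretical_setting()] with k > 0.
#' @return Scalar difference.
#' @export
delta_rtmme_vs_mrt <- function(s) {
  kd <- s$k * (1 + s$d)
  sum(s$lambdas * (s$lambdas * s$omega_diag - s$sigma2) / (s$lambdas + kd)^2)
}

#' MSE difference: RTMME minus ridge-M
#'
#' @param s A [theoretical_setting()].
#' @return Scalar difference; identically 0 at d = 0 or k = 0 since the two
#'   estimators then coincide.
#' @export
delta_rtmme_vs_ridgem <- function(s) {
  l <- s$lambdas; a2 <- s$alpha^2; om <- s$omega_diag
  kd <- s$k * (1 + s$d)
  sum((l^2 * om + kd^2 * a2) / (l + kd)^2) -
    sum((l^2 * om + s$k^2 * a2) / (l + s$k)^2)
}

#' MSE difference: RTMME minus M
#'
#' Computed as the difference of the closed-form sums; the per-component
#' numerator \eqn{-\Omega_{ii}(2\lambda_i k(1+d) + k^2(1+d)^2) +
#' k^2(1+d)^2\alpha_i^2} over \eqn{(\lambda_i + k(1+d))^2} is an exact
#' componentwise decomposition of the same quantity.
#'
#' @param s A [theoretical_setting()].
#' @return Scalar difference.
#' @export
delta_rtmme_vs_m <- function(s) {
  l <- s$lambdas; a2 <- s$alpha^2; om <- s$omega_diag
  kd <- s$k * (1 + s$d)
  sum((-om * (2 * l * kd + kd^2) + kd^2 * a2) / (l + kd)^2)
}

#' Componentwise k threshold for RTMME vs ridge-M superiority
#'
#' The printed closed form
#' \deqn{k_{1i} = \lambda_i\,[\sqrt{(d + 2\alpha_i^2 - \Omega_{ii})^2 +
#'   8\alpha_i^2\Omega_{ii}(d+1)} - (d + 2\alpha_i^2 - \Omega_{ii})] /
#'   (4\alpha_i^2(d+1)).}
#' This formula is exposed verbatim; [numeric_k_threshold()] provides an
#' independent numeric locator for the actual sign change of the RTMME vs
#' ridge-M MSE difference, because the closed form and the difference it is
#' meant to bound are not mutually consistent (in particular the difference
#' is identically zero at d = 0 while the formula returns a nonzero
#' threshold there). Use [k_threshold_report()] to tabulate the two.
#'
#' @param lambda_i Eigenvalue, > 0.
#' @param alpha_i2 Squared true coefficient, > 0.
#' @param omega_ii Omega diagonal entry, >= 0.
#' @param d Second biasing parameter, >= 0.
#' @return Scalar threshold, >= 0.
#' @export
k1i_threshold <- function(lambda_i, alpha_i2, omega_ii, d) {
  if (alpha_i2 <= 0) stop("degenerate component: alpha_i^2 must be positive")
  stopifnot(lambda_i > 0, omega_ii >= 0, d >= 0)
  b <- d + 2 * alpha_i2 - omega_ii
  lambda_i * (sqrt(b^2 + 8 * alpha_i2 * omega_ii * (d + 1)) - b) /
    (4 * alpha_i2 * (d + 1))
}

#' Numeric sign-change locator for the RTMME vs ridge-M difference
#'
#' Scans \eqn{k \mapsto \Delta_2(k)} on a 1000-point log-spaced grid over
#' (0, k_max] and refines every sign change by bisection to 1e-10. Serves
#' as the independent oracle for the closed-form threshold of
#' [k1i_threshold()].
#'
#' @param s A [theoretical_setting()] with d fixed (its k is ignored).
#' @param k_max Upper end of the scan interval.
#' @return Numeric vector of sign-change locations (possibly empty).
#' @export
numeric_k_threshold <- function(s, k_max = 100) {
  stopifnot(k_max > 0)
  f <- function(k) {
    delta_rtmme_vs_ridgem(theoretical_setting(
      s$lambdas, s$alpha, s$sigma2, s$omega_diag, k = k, d = s$d))
  }
  if (s$d == 0) return(numeric(0))
  ks <- exp(seq(log(k_max) - log(1e8), log(k_max), length.out = 1000))
  vals <- vapply(ks, f, numeric(1))
  roots <- numeric(0)
  sgn <- sign(vals)
  for (i in seq_len(length(ks) - 1)) {
    if (sgn[i] == 0) next
    if (sgn[i] * sgn[i + 1] < 0) {
      lo <- ks[i]; hi <- ks[i + 1]
      flo <- vals[i]
      while (hi - lo > 1e-10) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  roots
}

#' Check the sufficient condition for RTMME to beat MRT
#'
#' Evaluates both the aggregate condition \eqn{\sum\Omega_{ii} <
#' \sum\sigma^2/\lambda_i} and the componentwise condition
#' \eqn{\Omega_{ii} < \sigma^2/\lambda_i\ \forall i} underlying it, and
#' reports the realized MSE difference. The componentwise condition is the
#' one that guarantees a negative difference for all k > 0; the aggregate
#' condition alone does not, which is why both are returned as evidence
#' rather than a single boolean.
#'
#' @param s A [theoretical_setting()] with k > 0.
#' @return List with `sum_condition`, `componentwise_condition`, `delta1`.
#' @export
check_theorem1 <- function(s) {
  stopifnot(s$k > 0)
  list(
    sum_condition = sum(s$omega_diag) < sum(s$sigma2 / s$lambdas),
    componentwise_condition = all(s$omega_diag < s$sigma2 / s$lambdas),
    delta1 = delta_rtmme_vs_mrt(s)
  )
}

#' Evaluate the necessary-condition bound for RTMME vs M
#'
#' Reports \eqn{\sum_i k(1+d)\alpha_i^2/(2\lambda_i + k(1+d))},
#' \eqn{\sum_i \Omega_{ii}}, and the realized RTMME-minus-M difference.
#' Only the arithmetic is asserted: the direction of the inequality that
#' relates the two sums to the sign of the difference is reported, not
#' assumed.
#'
#' @param s A [theoretical_setting()].
#' @return List with `bound`, `omega_sum`, `delta3`.
#' @export
check_theorem3 <- function(s) {
  kd <- s$k * (1 + s$d)
  list(
    bound = sum(kd * s$alpha^2 / (2 * s$lambdas + kd)),
    omega_sum = sum(s$omega_diag),
    delta3 = delta_rtmme_vs_m(s)
  )
}

#' Tabulate the closed-form k threshold against the numeric locator
#'
#' For each supplied setting, records the componentwise closed-form
#' thresholds (their minimum) and the sign-change points found numerically,
#' plus whether the two agree within a tolerance. Intended as a report
#' artifact documenting the internal consistency of the printed threshold
#' formula; no agreement level is asserted.
#'
#' @param settings List of [theoretical_setting()] objects with d > 0.
#' @param k_max Scan range for the numeric locator.
#' @param tol Relative tolerance for calling the two thresholds equal.
#' @return data.frame with one row per setting: `min_k1i`,
#'   `first_numeric_root` (NA if none), `n_roots`, `agree`.
#' @export
k_threshold_report <- function(settings, k_max = 100, tol = 1e-6) {
  rows <- lapply(settings, function(s) {
    k1 <- vapply(seq_along(s$lambdas), function(i) {
      k1i_threshold(s$lambdas[i], s$alpha[i]^2, s$omega_diag[i], s$d)
    }, numeric(1))
    roots <- numeric_k_threshold(s, k_max)
    first <- if (length(roots)) roots[1] else NA_real_
    agree <- !is.na(first) &&
      abs(first - min(k1)) <= tol * max(1, abs(first))
    data.frame(min_k1i = min(k1), first_numeric_root = first,
               n_roots = length(roots), agree = agree)
  })
  do.call(rbind, rows)
}
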