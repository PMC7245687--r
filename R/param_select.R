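#' Huber's A-squared statistic
#'
#' Estimates the asymptotic variance factor of the M-estimator,
#' \deqn{\hat A^2 = \frac{s^2}{n-p-1} \frac{\sum_i \psi(e_i/s)^2}
#'   {[(1/n)\sum_i \psi'(e_i/s)]^2},}
#' with both sums over all n residuals. When every standardized residual
#' lies in the linear region of psi this collapses to the classical
#' residual variance with the n - p - 1 divisor.
#'
#' @param residuals Length-n residual vector from the converged M fit.
#' @param scale_s Robust scale s used by that fit, > 0.
#' @param n,p Observation and predictor counts.
#' @param control A [huber_control()] (supplies the tuning constant).
#' @return Scalar >= 0.
#' @export
estimate_A2 <- function(residuals, scale_s, n, p, control = huber_control()) {
  stopifnot(n > p + 1, scale_s > 0, length(residuals) == n)
  c0 <- control$tuning_c
  u <- residuals / scale_s
  denom <- mean(huber_psi_prime(u, c0))
  if (denom == 0) stop("degenerate psi-derivative sum: all residuals rejected")
  scale_s^2 / (n - p - 1) * sum(huber_psi(u, c0)^2) / denom^2
}

#' Diagonal of the estimated covariance of the canonical M-estimator
#'
#' \eqn{\hat\Omega_{ii} = \hat A^2 / \lambda_i}.
#'
#' @param A2 Huber's A-squared estimate, >= 0.
#' @param lambdas Positive eigenvalues.
#' @return Length-p vector.
#' @export
estimate_omega_diag <- function(A2, lambdas) {
  stopifnot(A2 >= 0, all(lambdas > 0))
  A2 / lambdas
}

#' Initial estimate of the second biasing parameter d
#'
#' \eqn{\hat d = \min_i \hat A^2 / \hat\alpha_{Mi}^2}.
#'
#' @param A2 A-squared estimate.
#' @param alpha_m Canonical M coefficients, all nonzero.
#' @return Scalar, > 0 when A2 > 0.
#' @export
d_initial <- function(A2, alpha_m) {
  if (any(alpha_m == 0)) stop("degenerate coefficient for d initialization")
  min(A2 / alpha_m^2)
}

#' Robust biasing-parameter k rules
#'
#' Aggregations of the per-component optimal values
#' \eqn{k_i = \hat A^2 / ((1+d)\hat\alpha_{Mi}^2)}:
#' * `HMR` (harmonic mean, the rule used in the selection procedure):
#'   \eqn{k = p\hat A^2 / \sum_i (1+d)\hat\alpha_{Mi}^2}
#' * `GMR` (geometric mean): \eqn{(\prod_i k_i)^{1/p}}
#' * `AMR` (arithmetic mean): \eqn{(1/p)\sum_i k_i}
#'
#' By the classical mean inequalities HMR <= GMR <= AMR.
#'
#' @param rule One of `"HMR"`, `"GMR"`, `"AMR"`.
#' @param A2 A-squared estimate, > 0.
#' @param d Second biasing parameter, >= 0.
#' @param alpha_m Canonical M coefficients, all nonzero.
#' @return Scalar k > 0.
#' @export
k_robust <- function(rule = c("HMR", "GMR", "AMR"), A2, d, alpha_m) {
  rule <- match.arg(rule)
  if (any(alpha_m == 0)) stop("degenerate coefficient")
  stopifnot(A2 > 0, d >= 0)
  p <- length(alpha_m)
  ki <- A2 / ((1 + d) * alpha_m^2)
  switch(rule,
    HMR = p * A2 / sum((1 + d) * alpha_m^2),
    GMR = exp(mean(log(ki))),
    AMR = mean(ki)
  )
}

#' Harmonic-mean estimate of d given k
#'
#' Harmonic mean of the per-component values
#' \eqn{d_i = \hat A^2/(k\hat\alpha_{Mi}^2) - 1}; may be negative, in which
#' case the selection procedure falls back to the initial d.
#'
#' @param k Biasing parameter, > 0.
#' @param A2 A-squared estimate.
#' @param alpha_m Canonical M coefficients.
#' @return Scalar (any sign).
#' @export
d_hmr <- function(k, A2, alpha_m) {
  stopifnot(k > 0)
  di <- A2 / (k * alpha_m^2) - 1
  if (any(di == 0)) stop("harmonic mean undefined: zero component d_i")
  length(di) / sum(1 / di)
}

#' Iterative robust selection of (k, d)
#'
#' Executes the four-step procedure:
#' 1. initial \eqn{\hat d = \min_i \hat A^2/\hat\alpha_{Mi}^2};
#' 2. \eqn{\tilde k_{HMR}} from the harmonic-mean rule with that d;
#' 3. \eqn{\tilde d_{HMR}} from the harmonic mean of per-component d given
#'    \eqn{\tilde k_{HMR}};
#' 4. keep \eqn{\tilde d_{HMR}} unless it is negative, in which case fall
#'    back to the Step-1 d.
#'
#' The selected d is not clipped to (0, 1); values above 1 are passed
#' through with a warning (set `clip_d = TRUE` to enforce the open unit
#' interval).
#'
#' @param data A `"regdata"` object.
#' @param control A [huber_control()].
#' @param clip_d If TRUE, clamp the final d into (0, 1) (at 1 - 1e-8).
#' @return List of class `"kd_selection"`: `A2`, `omega_diag`, `d_init`,
#'   `k_hmr`, `d_hmr`, `k_gmr`, `k_amr`, `k_final`, `d_final`,
#'   `used_fallback`, `alpha_m`, and a step-by-step `trace`.
#' @export
select_kd <- function(data, control = huber_control(), clip_d = FALSE) {
  stopifnot(inherits(data, "regdata"))
  cf <- canonical_decompose(data)
  mfit <- fit_huber_m(cf, data$y, control)
  A2 <- estimate_A2(mfit$residuals, mfit$scale_s, data$n, data$p, control)
  omega <- estimate_omega_diag(A2, cf$lambdas)
  am <- mfit$alpha_hat
  d0 <- d_initial(A2, am)
  k_h <- k_robust("HMR", A2, d0, am)
  d_h <- d_hmr(k_h, A2, am)
  used_fallback <- d_h < 0
  d_final <- if (used_fallback) d0 else d_h
  if (!clip_d && d_final > 1) {
    warning("selected d exceeds 1; passing through unclipped")
  }
  if (clip_d) d_final <- min(max(d_final, 1e-8), 1 - 1e-8)
  structure(list(
    A2 = A2, omega_diag = omega, alpha_m = am,
    d_init = d0, k_hmr = k_h, d_hmr = d_h,
    k_gmr = k_robust("GMR", A2, d0, am),
    k_amr = k_robust("AMR", A2, d0, am),
    k_final = k_h, d_final = d_final,
    used_fallback = used_fallback,
    m_converged = mfit$converged,
    trace = list(
      step1_d_init = d0, step2_k_hmr = k_h, step3_d_hmr = d_h,
      step4_fallback = used_fallback, step4_d_final = d_final
    )
  ), class = "kd_selection")
}

#' @export
print.kd_selection <- function(x, ...) {
  cat(sprintf("robust (k, d) selection: k = %.6g, d = %.6g%s\n",
              x$k_final, x$d_final,
              if (x$used_fallback) "  [fallback to initial d]" else ""))
  cat(sprintf("  A^2 = %.6g; d_init = %.6g; d_HMR = %.6g\n",
              x$A2, x$d_init, x$d_hmr))
  cat(sprintf("  k rules: HMR %.6g, GMR %.6g, AMR %.6g\n",
              x$k_hmr, x$k_gmr, x$k_amr))
  invisible(x)
}
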