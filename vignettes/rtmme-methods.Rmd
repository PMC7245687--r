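---
title: "Robust two-parameter ridge-type M-estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust two-parameter ridge-type M-estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmme)
```

## The problem

Ordinary least squares breaks down in two independent ways. Under
multicollinearity — near-linear dependence among predictor columns, i.e.
small eigenvalues of $X'X$ — coefficient variances blow up as
$\sigma^2/\lambda_i$. Under $y$-direction outliers, the quadratic loss lets
a single gross observation drag the whole fit. Ridge-type shrinkage fixes
the first problem; bounded-influence M-estimation fixes the second; neither
fixes both. This package implements an estimator family built to handle the
joint case, centred on the ridge-type modified M-estimator (RTMME).

## Model and canonical form

The model is $y = X\beta + \varepsilon$ with $E\varepsilon = 0$,
$\mathrm{Cov}(\varepsilon) = \sigma^2 I$. All fitting happens on the
*standardized* design: columns centred and scaled to unit Euclidean norm
(correlation form), response centred. Unit column norms make the
eigenvalues of $X'X$ comparable across sample sizes (they sum to $p$); the
intercept is absorbed by centring, and `back_transform()` recovers
raw-scale slopes and the implied intercept exactly.

Writing $X'X = T\Lambda T'$ with $\Lambda =
\mathrm{diag}(\lambda_1 \ge \dots \ge \lambda_p) > 0$, the canonical form is
$y = Z\alpha + \varepsilon$ with $Z = XT$, $\alpha = T'\beta$, $Z'Z =
\Lambda$. Because $T$ is orthogonal, $\mathrm{MSE}(\hat\beta) =
\mathrm{MSE}(\hat\alpha)$, so all theory is stated in canonical
coordinates. Eigenvectors are sign-fixed (first nonzero entry positive) so
$\alpha$ is reproducible across platforms; ties in eigenvalues are broken
by the stable sort order.

## The estimator family

All six estimators factor through two base fits and one shrinkage operator:

* **OLS**: $\hat\alpha = \Lambda^{-1}Z'y$.
* **M**: the Huber M-estimate, solving $\sum_i \psi(e_i/s)\,z_i = 0$.
* **Shrinkage** $R_{kd} = \Lambda(\Lambda + k(1+d)I)^{-1}$, applied
  componentwise: $\alpha_i \mapsto \lambda_i/(\lambda_i + k(1+d))\,\alpha_i$.

Composing them gives ridge ($R_{k0}\hat\alpha$), ridge-M
($R_{k0}\hat\alpha_M$), the modified ridge-type estimator MRT
($R_{kd}\hat\alpha$), and the RTMME ($R_{kd}\hat\alpha_M$). The family is a
reduction lattice — `RIDGE(0)` is OLS, `MRT(k, 0)` is `RIDGE(k)`,
`MRT(k, d)` is `RIDGE(k(1+d))`, `RTMME(0, 0)` is M, `RTMME(k, 0)` is
ridge-M — and the test suite asserts these identities exactly.

### Huber M-estimation choices

The source theory leaves $\psi$ and the scale estimator open, so the
package fixes them as follows and exposes them in `huber_control()`:

* $\psi(u) = \max(-c, \min(c, u))$ with $c = 1.345$, the standard constant
  giving 95% efficiency at the Gaussian model. $c \to \infty$ recovers OLS.
* Robust scale $s = \mathrm{MAD}/0.6745$ of the current residuals,
  re-estimated at every IRLS iteration (`mad_iterated`); `mad_fixed`
  freezes it at the initial OLS residuals for comparison. If the MAD
  degenerates (more than half the residuals exactly zero), the scale falls
  back to $1.2533 \times$ the mean absolute residual and the fit is
  flagged — never a silent `NaN`.
* IRLS starts at OLS, each step solving an exact weighted least-squares
  problem with weights $w_i = \min(1, cs/|e_i|)$; convergence when
  $\max|\Delta\alpha| / (1 + \max|\alpha|) < 10^{-8}$, capped at 100
  iterations with a `converged` flag. At every converged fit the
  estimating-equation residual $\|\sum_i \psi(e_i/s) z_i\|_\infty$ is
  recorded; the suite requires it below $10^{-6}$.

## MSE theory

`theoretical_mse()` evaluates the closed-form canonical MSEs; with
$\Omega = \mathrm{Cov}(\hat\alpha_M)$ (finite, diagonal entries
$\Omega_{ii}$):

$$\mathrm{MSE}(\hat\alpha) = \sigma^2 \sum_i \lambda_i^{-1}, \qquad
  \mathrm{MSE}(\hat\alpha_M) = \sum_i \Omega_{ii},$$
$$\mathrm{MSE}(\hat\alpha_{RTMME}) = \sum_i
  \frac{\lambda_i^2 \Omega_{ii} + k^2(1+d)^2\alpha_i^2}
       {(\lambda_i + k(1+d))^2},$$

and analogously for ridge, ridge-M, and MRT (replace $\lambda_i^2
\Omega_{ii}$ by $\sigma^2\lambda_i$ for the OLS-based versions, set $d = 0$
for the one-parameter ones). Three difference functions
(`delta_rtmme_vs_mrt()`, `_ridgem()`, `_m()`) give the pairwise
comparisons; each is verified against direct subtraction of the MSE
formulas on 1000 random settings, at $10^{-12}$ relative to the magnitude
of the cancelled terms (the subtraction oracle itself loses that much to
cancellation).

Two condition checkers return *evidence records* rather than booleans,
because the aggregate conditions in the source theory are weaker than the
componentwise conditions their proofs actually use:

* `check_theorem1()`: the componentwise condition $\Omega_{ii} <
  \sigma^2/\lambda_i\ \forall i$ guarantees RTMME beats MRT for every
  $k > 0$ (asserted on a full $k \times d$ grid in the tests); the
  aggregate condition $\sum\Omega_{ii} < \sum\sigma^2/\lambda_i$ alone does
  not, and a test exhibits the gap.
* `check_theorem3()`: reports $\sum_i k(1+d)\alpha_i^2/(2\lambda_i +
  k(1+d))$, $\sum_i \Omega_{ii}$, and the realized difference. The two
  printed statements of this condition point in opposite directions, so the
  checker asserts only the arithmetic.

The closed-form threshold `k1i_threshold()` for RTMME-vs-ridge-M
superiority is implemented exactly as printed. It is, however, internally
inconsistent with the difference it is meant to bound: the difference is
identically zero at $d = 0$ while the formula returns a nonzero threshold
there, and re-deriving the threshold from the printed quadratic inequality
yields different $(d{+}1)$ factors. The package therefore also provides
`numeric_k_threshold()` — a 1000-point log-spaced scan with bisection to
$10^{-10}$ — as the independent locator of the actual sign change, and
`k_threshold_report()` tabulates both side by side. No agreement level is
asserted; in practice the closed form does not locate the sign change, and
the report documents exactly that.

## Robust selection of $k$ and $d$

`select_kd()` runs the four-step rule on the converged M fit:

1. $\hat d = \min_i \hat A^2/\hat\alpha_{Mi}^2$,
2. $\tilde k_{HMR} = p\hat A^2 / \sum_i (1+\hat d)\hat\alpha_{Mi}^2$
   (harmonic-mean aggregation of the per-component optimal $k_i$;
   geometric- and arithmetic-mean versions are also computed and obey
   HMR $\le$ GMR $\le$ AMR),
3. $\tilde d_{HMR}$ = harmonic mean of $d_i = \hat A^2/(\tilde k_{HMR}
   \hat\alpha_{Mi}^2) - 1$,
4. keep $\tilde d_{HMR}$ unless negative, else fall back to $\hat d$.

Here $\hat A^2 = \frac{s^2}{n-p-1}\sum_i \psi(e_i/s)^2 \big/
\big[\tfrac1n\sum_i \psi'(e_i/s)\big]^2$ with both sums over all $n$
residuals — the printed index runs only to $p$, but the $\tfrac1n$ factor
makes the all-$n$ reading the only coherent one — and $\hat\Omega_{ii} =
\hat A^2/\lambda_i$. The selected $d$ is *not* clipped into $(0,1)$: the
steps never mention clipping, so values above 1 pass through with a
warning, and `clip_d = TRUE` enforces the open unit interval for users who
want the constraint under which the estimator was introduced. Step 2 uses
the scalar $\hat d$ from Step 1 (not per-component values), matching the
procedure's wording.

## The Monte Carlo engine

`run_scenario()` reproduces the standard comparison design for shrinkage
estimators:

* Design: $x_{ij} = (1-\rho^2)^{1/2} z_{ij} + \rho z_{i,p+1}$ with standard
  normal $z$, so raw column pairs have population correlation $\rho^2$;
  then standardized. $X$ is drawn **once per scenario** and held fixed
  across replications (the fixed-X convention of this simulation
  tradition); `redraw_design = TRUE` exposes the alternative.
* Truth: $\beta$ = the unit-norm leading eigenvector of $X'X$
  ($\beta'\beta = 1$), the configuration where shrinkage along the dominant
  eigendirection is least harmful.
* Response: $y_i = \sum_j \beta_j x_{ij} + \varepsilon_i$,
  $\varepsilon \sim N(0, \sigma^2)$. The intercept is taken as zero — the
  MSE criterion involves only the $p$ canonical slopes and the pipeline
  centres $y$, so any intercept would be absorbed.
* Contamination: none, $+20\sigma$ at observation 10, or $+20\sigma$ at 5
  and $-20\sigma$ at 10.
* Criterion: $\widehat{\mathrm{mse}} = R^{-1}\sum_j (\hat\alpha_j -
  \alpha)'(\hat\alpha_j - \alpha)$ on the canonical scale, with its Monte
  Carlo standard error.

Default grids are $k \in \{0.3, 0.7, 0.9\}$, $d \in \{0.2, 0.5, 0.8\}$,
2000 replications. Each scenario is fully reproducible from its own integer
seed via R's generator; replications within a scenario share one sequential
stream, which keeps scenarios independently re-runnable without any
cross-scenario coupling.

What the generator emulates — and what it does not: Gaussian errors,
exchangeable-correlation designs, and point-mass response contamination at
fixed positions. It has no leverage (x-direction) outliers, no heavy-tailed
error laws, and no heteroscedasticity, so passing tests certify behaviour
under the stated design, not under arbitrary real data.

A note on orderings: adding outliers to a clean scenario inflates the OLS
MSE (tested clean-vs-contaminated over 20 seeds), but the one- and
two-outlier schemes are *not* mutually ordered — their shifts act through
two nearly collinear design rows and can partially cancel in
$\Lambda^{-1}Z'\delta$ — so the tests deliberately do not assert
monotonicity between them.

## Problem sizes and numerical choices

The verification suite runs at sizes chosen to make every stochastic check
statistically decisive while keeping the whole suite near a minute:
reduction identities on 100 random instances ($n = 30$, $p = 4$, tolerance
$10^{-10}$); theory-vs-simulation agreement for ridge and MRT at 20,000
replications within 3 Monte Carlo standard errors (the linear-estimator
sampling is vectorized, so this is cheap); the contamination ordering at
$n = 20$, $p = 3$, $\rho = 0.99$, $\sigma = 1$, 500 replications — the
hardest cell of the factorial design, where RTMME's advantage is largest
and where an estimator that merely shrinks would fail the M-vs-OLS
comparison; 1000-setting sweeps for all algebraic identities. Degenerate
inputs are rejected early with named errors (singular or constant-column
designs, zero coefficients in the selection rules, all-rejected residuals
in $\hat A^2$).

## Limitations

* The theory treats $\Omega$ as known; in practice $\hat\Omega_{ii} =
  \hat A^2/\lambda_i$ is an asymptotic estimate, and the theorem checkers
  applied to data inherit its finite-sample error.
* Standard errors and inference for the shrunken coefficients are out of
  scope, as are generalized ridge (per-component $k_i$), Liu/Stein-type
  estimators, and leverage-robust (MM/S) estimation.
* The printed closed-form threshold $k_{1i}$ should be treated as
  documentation of the source theory, not as a working bound; use the
  numeric locator.
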