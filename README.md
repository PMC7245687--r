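# rtmme

Robust shrinkage estimation for linear regression when **multicollinearity
and y-direction outliers strike together** — the situation where plain
ridge regression is wrecked by the outliers and plain M-estimation is
wrecked by the collinearity. The audience is applied statisticians and
quantitative epidemiologists fitting linear models to observational data
with strongly correlated covariates and suspect response values.

## The estimator

Standardize the design (centred, unit-norm columns), rotate to canonical
form `Z = XT`, `Z'Z = Λ = diag(λ₁ ≥ … ≥ λ_p)`. Two base fits and one
operator generate the whole family:

* OLS: `α̂ = Λ⁻¹Z'y`
* Huber M: the IRLS solution of `Σ ψ(eᵢ/s) zᵢ = 0` (ψ clipped at
  c = 1.345, s = MAD/0.6745)
* shrinkage: `R_kd = Λ(Λ + k(1+d)I)⁻¹`, componentwise
  `λᵢ/(λᵢ + k(1+d))`

The **ridge-type modified M-estimator (RTMME)** is `R_kd α̂_M` — the
two-parameter shrinkage operator applied to the robust fit. Setting d = 0
gives ridge-M, using α̂ instead of α̂_M gives the modified ridge-type (MRT)
estimator, and so on down the lattice to OLS. Closed-form canonical MSEs,
condition checkers for the pairwise dominance results, a robust
harmonic-mean selection rule for (k, d), and a reproducible Monte Carlo
engine round out the package. See `vignettes/rtmme-methods.Rmd` for the
full account.

## Worked example

Fifty observations, three predictors at pairwise correlation 0.95² ≈ 0.90,
two gross response outliers (±20σ):

```r
library(rtmme)
set.seed(2024)
X <- generate_design(50, 3, 0.95, standardize = FALSE)
beta <- true_coefficients(X)                      # unit-norm truth
y <- inject_outliers(simulate_response(X, beta, 1), 2, 1)
dat <- standardize_design(X, y)

sel <- select_kd(dat)                             # robust (k, d)
#> robust (k, d) selection: k = 0.0423399, d = 0.0161634  [fallback to initial d]
#>   A^2 = 0.630092; d_init = 0.0161634; d_HMR = -2.61972
#>   k rules: HMR 0.0423399, GMR 0.156947, AMR 0.652382

fit <- fit_named("RTMME", dat, k = sel$k_final, d = sel$d_final)
#> RTMME fit (k = 0.0423399, d = 0.0161634)
#> canonical coefficients:  6.1494  1.5522 -0.3808
#> robust scale s = 0.7148, converged = TRUE (14 iterations)
```

`A^2` is Huber's variance factor for the M-fit (the robust analogue of
σ̂²); the selection ran the four-step harmonic-mean rule and fell back to
the initial d because the harmonic-mean d came out negative. On this draw
the canonical squared estimation error is 468.9 for OLS and 29.1 for the
RTMME at the selected (k, d) — the collinearity-and-outlier combination
that motivates the estimator.

A command-line wrapper covering `fit`, `select`, `theorems`, and
`simulate` is installed at `inst/cli/rtmme.R`:

```sh
Rscript inst/cli/rtmme.R fit --input data.csv --response y \
    --estimator rtmme --k 0.5 --d 0.2
```

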