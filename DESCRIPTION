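Package: rtmme
Title: Two-Parameter Ridge-Type Modified M-Estimation for Linear Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Robust shrinkage estimation for linear regression under joint
    multicollinearity and y-direction outliers. Implements the two-parameter
    ridge-type modified M-estimator (RTMME), which applies the modified
    ridge-type shrinkage operator to a Huber M-estimate, together with its
    comparator estimators (ordinary least squares, Huber M, ridge, ridge-M,
    and the modified ridge-type estimator), closed-form canonical mean squared
    error expressions with theorem-condition checkers, robust selection rules
    for the biasing parameters k and d, and a reproducible Monte Carlo engine
    for estimator comparison under correlated designs and contaminated
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
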