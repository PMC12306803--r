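Package: fgee
Title: One-Step Penalized Generalized Estimating Equations for Longitudinal Functional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Marginal function-on-scalar regression for longitudinal functional
    outcomes (continuous, binary, or count) via penalized functional generalized
    estimating equations (fGEE).  A consistent working-independence initial fit
    is refined by a single Newton-Raphson update under an exchangeable or AR(1)
    working correlation, using closed-form working-covariance inverses so that
    large covariance matrices are never materialized.  Includes fast K-fold
    cluster cross-validation for the smoothing parameters, robust sandwich and
    fast cluster-bootstrap variance estimators, pointwise and joint (max
    statistic) confidence bands, fully-iterated penalized GLS benchmarks for
    Gaussian outcomes, and synthetic-data generators for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    splines,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
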