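Package: refractQR
Title: Quantile Regression Analysis of Risk Factors for Refractive Error
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how genetic and environmental risk factors
    shift the conditional distribution of refractive error in childhood
    cohorts. Provides a conditional quantile regression fitter based on
    pinball (check) loss minimisation via a Frisch-Newton interior point
    method, ordinary least squares companions, percentile bootstrap
    confidence intervals, permutation contrasts of tail versus median
    effects, random-effects meta-regression of effect size on age, loess
    smoothing of effect-size profiles, chained-equation multiple imputation
    with Rubin pooling, phenotype and polygenic-risk-score coding utilities,
    and a synthetic cohort generator with closed-form quantile-specific
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    metafor,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
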