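Package: coxtrim
Title: Outlier-Robust Cox Regression with Sampling Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Cox proportional hazards models that are robust to influential
    outliers in the covariates via Bednarski-style influence trimming, and extends
    the trimmed estimator to sampled data (for example case-cohort designs) by
    incorporating inverse-probability-of-sampling weights into the estimating
    equation after the trimming iterations.  Provides the doubly-weighted sandwich
    variance estimator, trimming diagnostics, a Monte-Carlo study engine for
    contaminated Weibull survival data with case-cohort subsampling, broom-style
    tidiers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
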