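Package: safref
Title: Reference Models and Gender-Specific Cardiovascular Risk
    Stratification for Skin Autofluorescence
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building age- and gender-specific reference models
    of skin autofluorescence (SAF), a non-invasive optical proxy for
    tissue accumulation of advanced glycation endproducts.  Provides a
    calibrated synthetic cohort generator, stratified reference
    statistics with linear mean- and SD-versus-age curves, an
    SD-multiplier cardiovascular risk stratification scheme with skin
    reflectance specific strata for women, confounder-adjusted
    standardized mean differences with noncentral-t confidence intervals,
    descriptive cohort statistics with normality-gated test selection,
    and an orthogonal partial least squares regression (O-PLSR)
    implementation with k-fold cross-validation and permutation
    validation.  All results are returned as tibbles and every fitted
    object has tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
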