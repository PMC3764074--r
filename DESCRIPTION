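Package: plskrige
Title: Two-Stage Air Pollution Exposure Modeling with Measurement Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage air-pollution epidemiology. Stage one predicts
    long-term pollutant exposure at unmonitored locations by partial least
    squares (PLS) dimension reduction of geographic covariates combined with
    universal kriging fit by profile maximum likelihood, with 10-fold
    cross-validated RMSEP/R-squared model selection and a nearest-monitor
    baseline. Stage two fits a linear health model on the predicted exposures
    and corrects the naive inference for Berkson-like and classical-like
    measurement error via a parameter bootstrap, a partial parametric
    bootstrap, and SIMEX bias extrapolation. Includes a synthetic-study
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
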