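Package: sersdose
Title: Chemometric Calibration and Validation for SERS-Based Therapeutic
    Drug Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native chemometrics pipeline for quantifying drugs
    (meropenem as the worked case) in serum from surface-enhanced Raman
    spectroscopy (SERS) maps. Simulates SERS chip maps with
    concentration-dependent analyte bands, serum interferents and
    pixel-to-pixel hotspot heterogeneity; preprocesses spectra (cropping,
    asymmetric-least-squares background correction, top-fraction pixel
    reduction, dataset scaling); fits partial least squares regression
    (PLSR) calibrations with multivariate figures of merit (RMSEP, SEP,
    bias, sensitivity, analytical sensitivity, LoD, LoQ); validates models
    by leave-group-out resampling and permutation testing; and quantifies
    agreement against a reference method with Bland-Altman statistics and
    the minimal detectable change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
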