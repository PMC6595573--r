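Package: leafspec
Title: Leaf Trait Estimation from VIS-NIR-SWIR Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration of leaf physiological and chemical
    traits (chlorophyll, water content, specific leaf area, N, P, K) from
    full-range leaf reflectance spectra (350-2500 nm). Provides spectral
    preprocessing (noisy-edge trimming, Savitzky-Golay smoothing, 5-nm
    downsampling, train-statistics standardization), whole-spectrum
    calibration by NIPALS partial least squares regression and linear
    epsilon-insensitive support vector regression with 10-fold
    cross-validated model selection, narrow-band normalized-difference
    vegetation indices with an exhaustive two-band search, evaluation by
    R2, RMSE, MAPE and RPD with a four-tier RPD quality grading, and a
    seeded synthetic leaf-spectrum generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
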