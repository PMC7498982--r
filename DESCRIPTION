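Package: ptapls
Title: Regional Brain-Microstructure Patterns Predicting Post-Traumatic Amnesia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for relating coarse regional diffusion-MRI
    microstructure to the duration of post-traumatic amnesia (PTA) after
    severe traumatic brain injury. Aggregates fractional anisotropy and
    mean diffusivity over five bilateral brain regions with lesion
    exclusion, erosion and FA thresholding; removes healthy-control
    derived linear age trends; decomposes the regional pattern with a
    single-outcome partial least squares regression (PLS1) built from
    first principles; and validates prediction with leave-one-out
    cross-validation against a permutation null. A synthetic-cohort and
    synthetic-volume module provides ground-truth data so every stage is
    testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
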