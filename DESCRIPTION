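Package: dynalff
Title: Sliding-Window Dynamic ALFF Analysis for Resting-State fMRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the temporal variability of the amplitude of
    low-frequency fluctuations (ALFF) in resting-state BOLD fMRI.
    Implements temporal preprocessing (initial volume discard, head-motion
    quality control, nuisance regression, ideal band-pass filtering,
    Gaussian spatial smoothing), static and sliding-window dynamic ALFF
    maps (mean, SD and coefficient of variation across windows),
    covariate-adjusted voxelwise group inference with Gaussian
    random-field cluster-level correction and a label-permutation
    alternative, partial correlation of regional variability with
    clinical scores, and linear support-vector-machine classification
    with leave-one-out and k-fold cross-validation, ROC analysis and a
    label-permutation significance test.  A seeded synthetic-cohort
    generator produces two-group 4D BOLD-like data with a planted
    region of elevated dynamic-ALFF variability for end-to-end testing
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
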