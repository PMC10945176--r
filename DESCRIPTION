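Package: fairaug
Title: Audit and Mitigate Demographic Shortcut Learning in Medical Image
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for detecting and mitigating demographic shortcut
    learning in medical image classifiers. Generates subject-grouped
    synthetic 2D/3D image cohorts with planted demographic shortcuts,
    implements a stochastic distortion family (rotation, shear, scaling,
    fisheye) with chest X-ray and brain MRI presets, trains a small
    reference convolutional classifier on CPU, and evaluates fairness
    through association tests, demographic classifiability, grouped
    disparity metrics (AUC, binary cross entropy, expected calibration
    error, error rate, precision) with bootstrap confidence intervals,
    task-transfer probing, test-time augmentation, comparison debiasing
    methods, and gradient-based model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
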