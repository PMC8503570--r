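Package: cordsim
Title: Simulation-Based Power Analysis for Spinal Cord Atrophy from
    Cross-Sectional Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes spinal cord phantom volumes with analytically known
    cross-sectional area (CSA), simulates atrophy by isotropic (homothetic)
    scaling and scan-rescan variability by random rigid transforms composed
    into a single resampling, measures CSA by segmentation with slice-wise
    cosine angle correction along a spline-regularized centerline, and derives
    intra-/inter-subject variability, CSA error, and minimum sample sizes for
    unpaired (cross-sectional) and paired (longitudinal) designs, including a
    Monte Carlo estimate of sample-size variability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
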