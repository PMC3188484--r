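Package: oddfield
Title: Learned Lateral Association Fields for Contour Pop-Out
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis and analysis of the amoeba/no-amoeba contour-detection
    task. Generates parametric radial-frequency ("amoeba") targets fragmented
    among locally indistinguishable rotated clutter, converts binary line
    drawings into orientation-selective activity fields with
    difference-of-elliptical-Gaussian filters, learns Object-Distractor
    Difference (ODD) lateral-interaction kernels from pairwise edge
    coactivation statistics, relaxes activity fields by iterative
    multiplicative modulation, and evaluates contour detectability with
    two-alternative forced-choice trials, ROC/AUC analysis and
    chance-anchored saturating psychometric fits. Includes a parametric
    "Bowtie" association-field baseline and a difference-of-Gaussians
    front end for natural grayscale images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
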