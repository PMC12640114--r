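Package: blurriculum
Title: Developmental Visual Curricula and Time-Limited Plasticity in Small
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation of visual development as curriculum
    learning: trains small convolutional image classifiers under training
    regimens that order degraded (Gaussian-blurred or grayscale) and
    full-fidelity inputs over epochs, crossed with constant, step-decreasing,
    gradually decreasing and reduce-on-plateau learning-rate schedules that
    stand in for declining neuronal plasticity. Ships a procedural generator
    of labeled image sets whose class identity is carried redundantly by
    chromatic and fine spatial-frequency texture cues, evaluation batteries
    over test-time blur and hue-rotation sweeps, matched comparisons of
    decreasing versus constant learning rates, and representational analyses
    of first-layer receptive-field color and spatial-frequency tuning and
    layer-wise epoch-to-epoch weight dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
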