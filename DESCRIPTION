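Package: numreach
Title: Threshold-Free Modelling of Numerosity Comparison Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for reach-to-target numerosity
    comparison tasks. Implements a threshold-free decision model in which
    Weber-scaled evidence samples feed a sequential Bayesian estimate of the
    numerical difference, and an entropy-based certainty signal continuously
    weights a minimum-jerk optimal feedback controller. Also provides the
    traditional collapsing-bound accumulator for comparison, trajectory
    preprocessing (time normalization, flip-and-average, changes of mind,
    pull-back exclusion), psychometric Weber-fraction estimation, a synthetic
    trajectory generator with known ground truth, derivative-free parameter
    fitting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    readr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
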