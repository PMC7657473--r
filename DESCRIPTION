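Package: protrack
Title: Progressive and Frame-Wise Manual Video Tracking: Simulation,
    Performance Metrics and Piecewise Bayesian Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study manual digitization of markerless videos.
    Generates synthetic benchmark videos of a moving point with known
    ground-truth trajectories, drives frame-wise (click per frame) and
    progressive (cursor-following) tracking sessions either interactively
    or through simulated pursuit and click agents, computes tracking
    speed, accuracy and precision metrics, and fits piecewise-linear
    Bayesian changepoint models relating performance differences between
    the two tracking modes to point velocity, with WAIC and PSIS-LOO
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
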