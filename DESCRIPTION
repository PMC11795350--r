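Package: bindnet
Title: EEG Working-Memory Network Analysis Across the Adult Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for task EEG functional-connectivity networks
    over the adult lifespan, built around a visual short-term memory binding
    paradigm. Generates synthetic phase-coupled multichannel cohorts with
    age-dependent connectivity, segments and screens epochs with standard
    amplitude/step/gradient/flatline artifact criteria, estimates narrowband
    weighted phase lag index (wPLI) connectivity on a 1-48 Hz grid, derives
    thresholded weighted graphs and their integration, segregation and
    lattice-referenced small-world metrics, and models age effects with
    penalized-spline additive models followed by an age-partialled
    correlation screen under Benjamini-Hochberg false-discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    mgcv,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
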