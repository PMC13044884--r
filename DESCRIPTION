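Package: graphquant
Title: Semi-Quantification of LC-HRMS Screening Signals from Molecular
    Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates drug concentrations in whole blood from LC-HRMS
    screening signals without reference standards. The log
    signal-to-concentration ratio (beta) of a molecule is learned from its
    structure with a graph attention network over the heavy-atom graph
    (plus descriptor-based MLP, decision-tree and random-forest baselines),
    and a measured internal-standard-corrected peak area is then inverted
    into a concentration estimate. Includes ISTD correction, response-factor
    averaging with relative-deviation outlier filtering, SMILES
    featurization via OpenBabel, leave-one-out/k-fold/subset cross-validation
    harnesses with repeated-training spread, thresholded-accuracy metrics,
    a synthetic dilution-series generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
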