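Package: hiddenrates
Title: Hidden Rate-Class Markov Models of Trait Gain and Loss on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuous-time Markov models of a discrete character whose
    gain and loss rates are modulated by unobserved ("hidden") rate
    classes, fitted on time-calibrated phylogenies by maximum likelihood
    with multi-restart optimisation.  Includes AIC model comparison
    across one to five rate classes, precursor and three-state pathway
    models, joint (max-product) and marginal ancestral state
    reconstruction, edge-wise transition counting with per-clade
    tallies, fixed-ancestor analyses, gain/loss rate-grid scans, and a
    forward trait-history simulator with event-level ground truth.
    Developed for reconstructing the evolution of root nodule symbiosis
    across the nitrogen-fixing clade of flowering plants, but applicable
    to any binary or three-state trait on a rooted tree with branch
    lengths in time units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
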