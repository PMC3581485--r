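Package: shoctscan
Title: Profile-HMM Discovery Pipeline for Short C-Terminal Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the computational pipeline used
    to discover and validate short C-terminally biased protein domains such as
    SHOCT: seed-alignment to profile hidden Markov model construction, local
    multihit forward/Viterbi bit scoring with dual (sequence and per-domain)
    inclusion thresholds, jackhmmer-style iterative expansion from a single
    query, a reversed-alignment decoy control for empirical threshold
    calibration, and downstream censuses of domain position, taxonomy,
    architecture and per-protein copy number. Ships a synthetic-proteome
    generator that plants a conserved ~30-residue two-helix motif family with
    full ground truth, so every stage is testable end to end without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
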