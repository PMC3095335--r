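Package: seldiv
Title: Selection and Functional Divergence Analysis of Codon Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular-evolution analysis of plant gene
    subfamilies such as the NIP III (NIP2) aquaporins: back-translation of a
    protein alignment into a filtered codon alignment, fourfold-degenerate
    transversion (4DTv) distances for paralog dating, neighbor-joining trees
    with bootstrap support and a strict-clock age estimate, GY94-style codon
    site models (M0/M3/M7/M8) and branch models with likelihood-ratio tests
    and empirical-Bayes detection of positively selected sites, Type-I and
    Type-II functional-divergence estimation between clades, and a
    mutual-information scan for specificity-determining positions with a
    Bernoulli-estimator cutoff. A synthetic-data module simulates codon
    alignments under site-class omega distributions, per-cluster rate shifts,
    group-specific column compositions and diverged paralog pairs, so every
    stage of the pipeline is testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
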