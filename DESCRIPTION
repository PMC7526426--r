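Package: tmsta
Title: Scalable Pairwise and Progressive Multiple Protein Structure Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for protein structure comparison from
    C-alpha traces. Stage one computes TM-align-style pairwise structure
    alignments (seed generation, Needleman-Wunsch dynamic programming over
    structure-derived scores, iterative superposition refinement, TM-score
    maximisation) for all structure pairs, in parallel over ordered work
    partitions with a strict determinism contract, and summarises them as a
    TM-score-derived distance matrix. Stage two builds a UPGMA guide tree
    stored as an indexed binary tree and progressively merges profiles from
    the leaves to the root to produce a multiple structure alignment with
    core-column metrics (average RMSD, average TM-score). A deterministic
    synthetic-structure generator provides C-alpha backbones and perturbed
    families with known residue correspondences so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
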