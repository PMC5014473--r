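Package: recscan
Title: Exploratory Detection and Analysis of Recombination in Nucleotide Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free detection of individual recombination events in
    multiple nucleotide sequence alignments by exhaustive triplet scanning with
    a battery of heuristic signal statistics (pairwise-identity rank inversion,
    sliding-window chi-square, informative-site chi-square, sister-scanning
    z-scores, bootscan window phylogenies, and a maximum-descent random-walk
    statistic), two-state hidden Markov model breakpoint placement with
    highest-posterior-density confidence intervals, minimal-event assembly by
    iterative recombinant disassembly, and downstream breakpoint-pattern
    statistics: permutation hot/cold-spot tests, breakpoint pair matrices,
    site-pair co-inheritance matrices, genome-feature association tests, and
    sliding-window phylogenetic compatibility matrices (Robinson-Foulds and
    SH-like RELL support). Includes a tree-based alignment simulator with
    truth-labelled implanted recombination events, recombination-aware
    alignment export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
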