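Package: motifsieve
Title: Monte Carlo Subset Sampling for DNA Motif Discovery in Corrupted
    Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers short DNA sequence motifs in data sets where many
    entries contain no motif at all (for example fixed windows around
    ChIP-seq or ChIP-chip peaks).  A zero-or-one-occurrence-per-sequence
    (ZOOPS) expectation-maximization motif finder and a Gibbs sampler are
    run on many random subsets of the input, each subset is refined into a
    "related subset" by one of three protocols (including an iterative
    fixed-point scheme that alternates motif fitting with whole-set
    scanning), the resulting motifs are filtered by a shuffle-null
    E-value, clustered into a UPGMA tree under the average log-likelihood
    ratio (ALLR) column metric, and dense motif families are condensed
    into familial profiles that are mapped back onto every input sequence.
    Includes a planted-motif simulator with ground truth and entry-level
    sensitivity, specificity and F-measure scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
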