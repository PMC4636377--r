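Package: evoreseq
Title: Mutational Dynamics in Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of long-term evolve-and-resequence experiments in
    asexual microbial populations: filtering and classification of
    time-resolved variant tables, clustering of allele-frequency
    trajectories into linked-mutation cohorts and Muller-diagram
    reconstruction, clonal-interference statistics, copy-number and
    aneuploidy calling from binned read-depth tracks, binomial tests for
    recurrently mutated genes, selection-coefficient estimation from
    competition assays, and probabilistic sub-network inference over
    gene-interaction graphs. Includes a Wright-Fisher style simulator of
    the full experiment that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
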