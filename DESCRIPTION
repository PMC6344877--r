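Package: regulonkin
Title: Kinetic Modeling and Genomic Mapping of Bacterial Sigma-Factor Regulons
Version: 0.1.0
Authors@R:
    person("Regulon", "Maintainers", email = "maintainers@regulonkin.org",
           role = c("aut", "cre"))
Description: Tools for deciding which genes bound by a bacterial sigma factor
    are actually under its kinetic control. Expression time series are
    normalized and smoothed with least-squares cubic splines, then each
    candidate target is fitted with a cascade of transcription-kinetics
    ordinary differential equation models of increasing complexity: constant
    synthesis, direct sigmoidal regulation by the sigma factor, and regulation
    by an equilibrium sigma-factor/cofactor complex whose concentration
    follows from mass action. Parameters are estimated by simulated annealing
    (compiled core), with permutation-based false-positive estimation.
    Companion modules filter ChIP-seq peaks, assign them to genes and operons
    by summit-to-start-codon distance, compute promoter -10-element anchored
    dinucleotide statistics with Fisher enrichment tests, and generate fully
    synthetic benchmark data sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
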