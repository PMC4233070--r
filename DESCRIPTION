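Package: mirfruit
Title: Small RNA Sequencing Analysis of miRNAs Across Fruit Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for plant miRNA discovery and expression
    profiling from staged small RNA sequencing libraries. Implements read
    cleaning (adapter, poly-A, quality, length), collapsing to unique
    sequences, priority-based categorization against ncRNA, repeat and gene
    annotations, exact-match identification of conserved miRNAs against a
    miRBase-style reference, novel miRNA prediction by genomic window
    excision, Nussinov-style energy folding and hairpin criteria, TPM
    normalization with digital-count (Audic-Claverie) differential
    expression across developmental stages, rule-based miRNA target
    prediction with G:U wobble weighting, genomic miRNA cluster detection,
    annotation-term enrichment factors, and comparative ddCt qPCR
    quantification. Ships a synthetic-data generator that plants miRNA
    loci, clusters, stage-dependent abundance profiles and target sites
    with full ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
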