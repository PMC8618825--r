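Package: genorig
Title: Synteny-Based Dating, Origin-Mechanism Classification and
    Selection Analysis of Lineage-Specific New Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for the study of new gene origination on a
    dated ladder phylogeny. Genes of a focal genome are dated onto
    phylogenetic branches from reciprocal-best whole-genome alignments
    (synteny-based dating), lineage-specific genes are classified as
    DNA-mediated duplicates, retrogenes or de novo genes, selective
    constraint is tested with fixed-omega codon-model likelihood-ratio
    tests, and expression evidence and left/right asymmetric expression are
    called from FPKM and count matrices. A forward genome-evolution
    simulator with planted, dated gene-birth events provides fully
    verifiable inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    seqinr
Config/testthat/edition: 3
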