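Package: smallmir
Title: Discovery of Putative MicroRNA from Small RNA-Seq with
    Conservation-Based Functionality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering putative novel microRNA
    (miRNA) from deep small RNA sequencing data and assessing their
    functionality through sequence conservation. Raw 36-nt adapter-bearing
    reads are trimmed, complexity-filtered, collapsed and mapped exactly to a
    genome; mapped loci are folded with a local weighted base-pairing engine
    to find unbranched precursor stem-loops; candidates are scored by a
    structure classifier with dinucleotide-shuffled folding controls and by a
    read-signature permutation score; conserved candidates (mean per-base
    conservation >= 0.8) are grouped into seed families whose
    reverse-complement 7-mer target sites in 3'UTRs are tested for excess or
    deficit of conservation against scrambled-seed controls with an exact
    binomial test, a motif rank score, and family-proportion simulations.
    A synthetic-data generator with planted ground truth (precursors, star
    reads, conserved and avoided seeds) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    randomForest,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
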