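Package: wssgwas
Title: Weighted Single-Step GBLUP Genome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) association analysis for
    populations where only a subset of pedigreed animals is genotyped.
    Builds pedigree (A, A22) and genomic (G) relationship matrices and the
    combined H inverse, estimates variance components for the animal model
    y = Xb + Za + e by Gibbs sampling with convergence diagnostics
    (Geweke, Heidelberger-Welch) and highest-posterior-density summaries,
    back-solves SNP effects from genomic breeding values, iteratively
    re-weights SNPs by their explained variance, and partitions additive
    genetic variance into windows of adjacent SNPs for QTL detection.
    Includes a pedigree/genotype/phenotype simulator with known truth,
    genotype and contemporary-group quality control, PLINK text and TSV
    readers and writers, and GFF3-based gene annotation of candidate
    windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
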