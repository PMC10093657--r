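Package: csscan
Title: Composite Selection Signals Genome Scans on SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects signatures of recent positive selection in a target
    population relative to reference populations from phased biallelic SNP
    data. Computes per-SNP Weir-Cockerham Fst, derived allele frequency
    differences polarized by an outgroup panel, and the cross-population
    extended haplotype homozygosity statistic (XP-EHH), then combines them
    into the rank-based composite selection signals (CSS) index, smooths the
    index along the genome, calls significant regions at a top-fraction
    threshold, and annotates overlapping genes. Includes quality-control and
    allele-harmonization utilities for PLINK text and phased VCF input, and a
    synthetic-data generator that produces diverged populations carrying
    known selective sweeps so the whole pipeline can be validated against a
    recorded truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
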