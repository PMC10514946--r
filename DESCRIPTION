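Package: divscan
Title: Genomic Divergence Scans from SNP Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window scans of the genomic landscape of divergence for
    small structured cohorts genotyped by sequencing. Reads and filters VCF
    genotypes, computes Weir-Cockerham fixation-index variance components,
    windowed nucleotide diversity and linkage-disequilibrium r-squared on a
    100 kb / 10 kb sliding grid, calibrates outlier thresholds by whole-genome
    permutation, merges consecutive outlier windows into divergence peaks with
    flanking-region gene and QTL annotation, and summarises population
    structure (genotype PCA, Evanno delta-K, membership-threshold assignment).
    Includes a Balding-Nichols cohort simulator with planted divergence
    islands and ground truth for benchmarking scan recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
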