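Package: tsMultiome
Title: Tissue-Specific Genes and Open Chromatin Regions from Multi-Tissue
    scRNA-seq and ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls tissue-specific genes and tissue-specific open chromatin
    regions (TS OCRs) from multi-tissue single-cell RNA-seq and bulk ATAC-seq
    by exhaustive pairwise ("1 versus 1") differential intersection, integrates
    chromatin accessibility with mRNA expression through region-class-averaged
    log2 fold changes (promoter, intragenic, intergenic), and screens for genes
    correlated with a target gene at the single-cell level. Includes single-cell
    quality control (UMI and mitochondrial filters, log-normalization,
    marker-panel contaminant removal, per-tissue downsampling), native
    differential statistics (tie-corrected rank-sum, median-of-ratios size
    factors, a simplified negative-binomial Wald test with binned
    method-of-moments dispersion), descriptive reporting (sample ordination,
    Spearman correlation by region class, hierarchical tissue proximity), and a
    synthetic five-tissue multi-omic data generator with a planted-truth
    manifest for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    jsonlite,
    ape,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
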