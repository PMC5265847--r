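Package: omnilevel
Title: Multi-Omics Evidence Levels for Hyperactivated Genes in Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Screens tumor/normal multi-omics cohorts for abnormally hyperactivated
    genes across five modalities (gene expression, copy number, DNA methylation,
    miRNA-target loss of repression, and somatic mutation enrichment), integrates the
    per-modality calls into nested evidence levels, and tests called gene lists for
    overlap with gene-set collections. Includes a self-contained statistical kernel
    (exact rank tests, Fisher exact test, Benjamini-Hochberg FDR, hypergeometric
    overlap), readers and writers for SEG, MAF, BED, GMT and TSV matrix formats, and
    a seeded synthetic multi-omics study generator with planted effects and a
    ground-truth table for end-to-end benchmarking.
License: MIT
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
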