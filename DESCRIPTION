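Package: dmc450
Title: Differential CpG Methylation and Genomic-Context Enrichment for
    Two-Group Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for two-group analysis of Infinium
    450K-style DNA methylation beta-values: probe-level quality and
    annotation filtering with an auditable exclusion ledger, calling of
    differentially methylated CpGs (DMCs) by Welch's t-test with
    Benjamini-Hochberg correction and an effect-size gate, annotation of
    probes into gene regions, CpG-island context (island/shore/shelf/open
    sea) and enhancer status, contingency-table enrichment statistics
    (odds ratios with Katz log-scale confidence intervals and
    Yates-corrected chi-square tests), mapping of DMCs to transcription
    start sites with hypergeometric gene-set over-representation, and
    sample-level exploratory analyses (classical multidimensional scaling,
    hierarchical clustering, variance tests). Includes a synthetic-data
    generator that emulates the probe annotation structure and beta-value
    distributions of a 450K experiment so the whole pipeline is testable
    without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    car,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
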