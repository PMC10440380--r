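Package: wdliver
Title: Early and Late Western-Diet Liver Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for dissecting early (1 week) versus late
    (40 weeks) western-diet effects on the mouse liver transcriptome in a
    2x2 diet-by-time design: quantile normalization, per-timepoint WD/LFD
    differential expression with fold-change and FDR gates, two-way ANOVA
    diet-by-time interaction screening with Benjamini-Hochberg control,
    k-means clustering of per-group geometric-mean expression with
    per-cluster summaries, single-cell UMI reanalysis deriving uniquely
    expressed cell-type marker catalogs, assignment of bulk genes to cell
    types via those catalogs, hypergeometric over-representation and
    preranked gene-set enrichment, and a negative-binomial synthetic-data
    generator with ground-truth ledgers so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
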