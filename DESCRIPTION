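Package: osntools
Title: Single-Cell Analysis of Olfactory Sensory Neurons and Crispant Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for single-cell RNA-seq analysis of zebrafish
    olfactory sensory neurons (OSNs): quality-control filtering, marker-based
    maturity staging and immune-contaminant flagging, per-cell odorant-receptor
    (OR) tabulation with predominant-OR assignment, Spearman co-expression
    analysis of OR genes with genomic block detection, negative-binomial Wald
    tests for clade-versus-clade differential expression with
    Benjamini-Hochberg correction, and candidate curation by membrane/secreted
    annotation. Also provides combination of per-guide CRISPR F0 knockout
    scores under independence and one-tailed Fisher's exact statistics for
    axon-targeting experiments, plus a fully seeded synthetic-data generator
    with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
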