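Package: superstate
Title: Chromatin Classes, Transcriptional States and Superstate Analysis for
    Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for paired single-cell ATAC and RNA data that
    asks whether chromatin accessibility defines fewer, broader cell
    populations ("chromatin classes") than transcription does, so that one
    class acts as a superstate encompassing several transcriptional cell
    states. Covers barcode-aware read deduplication, summit-centered 200-bp
    peak consolidation, fragment counting, cell and feature quality control,
    TF-IDF/LSI chromatin clustering with a pluggable batch-adjustment
    contract, cross-modal k-nearest-neighbor label transfer, the class-by-
    state Fisher odds-ratio matrix with a conditional maximum-likelihood
    estimate, pairwise linear-discriminant AUC of state separability in
    chromatin space, mixed-logistic and negative-binomial likelihood-ratio
    differential tests, signed per-cell accessibility scores, hypergeometric
    motif enrichment, and fine-mapped variant prioritization. A seeded
    synthetic multiome generator with nested class/state structure supports
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    data.table,
    jsonlite,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
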