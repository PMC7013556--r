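Package: trophodiff
Title: Time-Course Transcriptomics of Villous Trophoblast Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for time-course expression
    analysis of villous cytotrophoblast differentiation into the
    syncytiotrophoblast. Provides empirical-Bayes moderated differential
    expression against day-0 and previous-day baselines, Fisher exact
    enrichment machinery (chromosome, module, and gene-set collections),
    weighted co-expression module detection with topological overlap,
    enrichment-guided selection of a high-expression-change threshold with
    temporal clustering, transcription-regulator network inference from
    co-expression and from DNaseI footprint/motif/TSS intervals,
    topology-propagated pathway impact analysis, and a disease overlay that
    flags transcription regulators changing discordantly in preterm
    preeclampsia. A seeded synthetic-data generator with planted ground
    truth makes every stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    igraph
Config/testthat/edition: 3
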