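Package: chillregnet
Title: Phase-Structured Transcriptional Regulatory Network Inference from
    Chilling-Stress Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct a phase-structured transcriptional
    regulatory network from a chilling-stress (10 degrees C) expression time
    course paired with an exogenous hydrogen peroxide (oxidative mimic)
    experiment. The pipeline calls induced and repressed genes from
    thresholded log2 ratios with per-time-point significance, segments
    induction waves and assigns early/intermediate/late response phases,
    clusters upregulated non-transcription-factor genes by k-means,
    discovers over-represented promoter motifs per cluster with a
    ZOOPS-style expectation-maximisation algorithm, scores cis-element
    class enrichment against a packaged catalog, links enriched element
    classes to temporally compatible transcription-factor families as
    ranked network edges with oxidative-mediation labels, and tests
    co-localization of upregulated transcription factors with quantitative
    trait locus intervals by one-sided Fisher exact tests. A synthetic-data
    generator with full ground truth (phases, planted promoter motifs,
    planted regulators, planted QTL enrichment) makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
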