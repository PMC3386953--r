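Package: exonsplice
Title: Exon-Array Differential Splicing with Splicing-Index Testing and
    Splicing-Factor Footprint Enrichment
Version: 0.1.0
Authors@R: person("exonsplice", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for separating transcription-level
    regulation from alternative-splicing regulation on exon microarrays.
    Provides a synthetic exon-array experiment generator with planted
    expression and exon-inclusion changes, probe-level preprocessing
    (additive background correction, cross-hybridizing probe removal,
    median-polish probe-affinity estimation, detection-above-background
    presence calls), transcript-level summarization with empirical-Bayes
    moderated-t differential expression and fold-change filtering, per-probe
    splicing indices with two independent probeset-level differential
    splicing tests (ANOVA and moderated-t) combined by a dual-test consensus
    rule, and hypergeometric gene-set overlap ("splicing-factor footprint")
    plus over-representation analysis with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tools,
    limma
Config/testthat/edition: 3
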