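Package: tfimpact
Title: Transcription Factor Impact Scoring from ChIP-Seq Binding and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("tfimpact", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Ranks transcription factors by their impact on a biological
    transition (e.g. the epithelial-to-mesenchymal transition) by
    integrating ChIP-Seq binding sites with two-group differential
    expression. Computes a distance-decay regulatory potential per gene
    from peak-to-TSS distances, derives top-N regulated gene sets,
    scores each factor by the fraction of regulated genes that are up-
    or down-regulated with hypergeometric significance, filters
    cross-cell-line consensus peaks, and runs a two-stage functional
    cross-enrichment over GMT gene sets. Includes a deterministic
    synthetic-data generator with planted regulators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
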