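Package: regmra
Title: Master Regulator Discovery from Multi-Platform Expression Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying transcription factors that
    act as master regulators of a transcriptional phenotype in heterogeneous
    stem-cell expression collections. Harmonizes gene-by-sample matrices from
    multiple platforms into one standardized dataset, classifies samples into
    transcriptional subtypes by single-sample gene set enrichment with
    resampling-based p-values, performs batch-aware moderated differential
    expression, infers transcription-factor regulons by mutual information
    with a pooled permutation null and data-processing-inequality pruning,
    ranks candidate master regulators by hypergeometric regulon-signature
    overlap and one-tail gene set enrichment, stratifies survival cohorts by
    expression percentiles with Kaplan-Meier and log-rank comparisons, and
    quantifies sphere-forming cell frequency from limiting-dilution assays
    under the single-hit Poisson model. A synthetic-data module generates all
    pipeline inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
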