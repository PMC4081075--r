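Package: cofbal
Title: Transcription-Factor Co-Occupancy and Cofactor-Balance Subgroup Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link genome occupancy by a transcription factor and its
    cofactors (peak-centre overlap clustering, occupancy signatures,
    centre-distance profiles, binned occupancy correlation, knockdown
    differential occupancy, consensus-motif counting) to expression-defined
    tumour subgroups (marker-gene quadrant splits, per-cohort differential
    expression, cross-cohort consensus meta-profiles, hypergeometric and
    bootstrap gene-set enrichment, Kaplan-Meier survival and mutation
    association). Includes a synthetic-data module that generates every input
    the pipeline consumes with planted, recoverable structure, and a
    configuration-driven orchestration layer with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
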