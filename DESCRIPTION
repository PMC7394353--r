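Package: riboshift
Title: Transcription-Translation Interplay Across Growth-Phase Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of coupled transcriptional and translational regulation
    across growth-phase transitions from paired RNA-seq and ribosome-profiling
    count tables. Provides a self-contained differential-abundance stage,
    regulatory-class assignment (transcriptional, compensatory, translational),
    translational-efficiency regression with residual and permutation
    statistics, ribosomal-protein stoichiometry deviation detection,
    bootstrapped binary-distance clustering of co-regulated module membership
    with condition-specific similarity scoring, and module detection on
    bait-prey protein-interaction networks. A synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
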