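Package: paralogGI
Title: Genetic-Interaction Analysis of Multiplex CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring genetic interactions in pooled multiplex
    CRISPR knockout screens. Implements construct-level read counting and
    normalization (pseudocount, depth scaling, per-group mode centering),
    delta-log-fold-change and modified Cohen's D scoring of paralog
    synthetic lethality, cross-study meta-analysis with Jaccard-based
    platform weights and gold-standard candidate selection, an additive
    regression null model for multi-guide Cas12a arrays with
    position-effect diagnostics, paralog family selection and four-guide
    array/synthesis-oligo design, gene-level screen quality control
    against essential/non-essential reference sets, and seeded
    synthetic-data generators that emulate the statistical structure of
    these screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
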