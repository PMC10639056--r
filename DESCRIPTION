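Package: promforge
Title: Promoter Engineering Toolkit: TFBS Scanning, In Silico Saturation
    Mutagenesis and Screening Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational engineering of yeast promoters.
    Provides an upstream-anchored promoter sequence model with
    mutation-notation parsing, position weight matrix (PWM)
    representation and similarity-score scanning of both strands,
    exhaustive in silico single-nucleotide saturation mutagenesis with
    differential transcription-factor-binding-site (TFBS) gain/loss
    mapping, rule-based variant design (point mutations, sliding-window
    deletions, segmental duplications), a stochastic error-prone PCR
    library simulator, and screening statistics with modified Z-score
    outlier filtering, relative-fluorescence normalisation and
    secreted-protein yield fold-changes. Seeded synthetic-data
    generators (PWM sets, fixture promoters with planted motifs,
    planted-effect screening datasets) make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
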