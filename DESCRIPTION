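Package: fishbeam
Title: Localized Heavy-Ion Irradiation Analysis for Small Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for localized heavy-ion irradiation
    experiments in small teleost fish (medaka). Converts between particle
    fluence and absorbed dose via linear energy transfer (LET), models
    depth-LET (Bragg) profiles and the irradiated band of an oval body
    cross-section, extracts beat-by-beat and steady-state heart rates from
    high-speed video region-of-interest intensity traces, reconstructs and
    quantifies organ volume and blood-cell composition from labeled serial
    histological sections with translation registration, and reproduces
    group statistics (one-way ANOVA, Tukey HSD, including an
    ANOVA-from-summary-statistics variant). Ships seeded synthetic-data
    generators for beating-heart videos and jittered kidney section stacks
    so every stage is testable against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
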