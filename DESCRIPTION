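Package: metfinger
Title: Metabolic Fingerprinting of Methionine-Restricted Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for LC/MS metabolic fingerprinting of cell
    cultures under methionine restriction. Takes integrated peak areas
    through external-standard normalization, compartment-specific percent
    conversion (control-medium baseline for supernatants, per-experiment
    series maximum for cell pellets), cross-experiment averaging and
    pathway-class aggregation, to a differential metabolic fingerprint at a
    reference timepoint, a directional match score for candidate low-energy-
    metabolism inducers, a five-component low-energy-metabolism footprint
    score, and crystal-violet relative-cell-number summaries. A synthetic
    data module emulates the full study design (conditions x compartments x
    timepoints x replicates x experiments) with known ground truth so every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
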