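Package: comboscreen
Title: Fixed-Ratio Drug Combination Screening and Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput drug-combination viability
    screens in short-term tumor cultures. Normalizes raw plate absorbance to
    percent viability, fits median-effect concentration-response models
    anchored at clinical peak plasma concentration (C_max), constructs
    fixed-ratio two-drug combinations at C_max and 10% C_max, scores drug
    interactions with the Chou-Talalay combination index across the
    fraction-affected range, ranks treatments across model lines by
    trapezoidal area under the viability curve, and compares in vivo tumor
    growth arms with a seeded randomization (permutation) test with
    Bonferroni correction. Ships a synthetic-data generator with known
    ground truth (Loewe-additive, synergistic and antagonistic interaction
    surfaces; stochastic tumor growth) for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
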