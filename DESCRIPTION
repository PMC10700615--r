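Package: marshmf
Title: Multifunctionality and Trophic-Cascade Analysis for Coastal
    Wetland Restoration Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plot-based coastal wetland restoration
    experiments with manipulated predator (shorebird) and grazer (crab)
    pressure. Derives twelve ecosystem-function values (biological,
    physical, and biogeochemical) from raw plot measurements, summarises
    them with averaged and Hill-number ("effective number of functions")
    multifunctionality indices, runs the standard treatment-comparison
    statistics (one-way ANOVA with Tukey HSD and compact letter displays,
    pairwise Wilcoxon and proportion tests, AICc model selection, Spearman
    correlation), and provides log-response-ratio effect-size machinery
    with DerSimonian-Laird random-effects pooling, meta-regression against
    bird abundance, and historical grazer back-projection. A seeded
    synthetic-data generator emulates the 4-treatment x 8-plot field design
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
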