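Package: panelburden
Title: Rare-Variant Burden, Firth Association and Cumulative Risk for
    Panel-Sequenced Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analyses of targeted gene-panel
    sequencing studies of breast cancer susceptibility: rule-based
    classification of protein-truncating and rare missense variants,
    per-gene and per-domain carrier burden tabulation with subtype and
    family-history stratification, Firth bias-reduced penalized-likelihood
    logistic regression with covariate adjustment and carrier-by-age
    interaction models, and cumulative (absolute) risk curves obtained by
    constraining age-specific odds ratios to population incidence rates.
    Includes a synthetic-cohort generator emulating the design of a
    population-based case-control study so every stage is testable without
    access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
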