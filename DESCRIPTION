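Package: akdsignal
Title: Pharmacovigilance Signal Detection for Drug-Associated Acute Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse-drug-reaction
    reports with an acute kidney disease (AKD) case definition: a notification data
    model with deduplication and ingredient normalization, a MedDRA-style
    preferred-term case definition, report-level 2x2 contingency tables with the
    reporting odds ratio (ROR, Woolf confidence intervals) and the Bayesian
    information component (IC, with its lower credibility bound IC025), a two-stage
    screen (IC025 > 0 confirmed by ROR > 1), a 0-5 bibliographic nephrotoxicity
    score with three-level classification, descriptive frequency tables (terms, ATC
    classes, ingredients, demographics, seriousness, fatal outcomes), and a seeded
    synthetic report generator with planted drug-event signals of known strength for
    validating the whole pipeline without access to a proprietary database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
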