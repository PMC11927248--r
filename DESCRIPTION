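Package: rrtscore
Title: Validation and Scoring of Responsiveness and Respectful Maternity
    Care Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Psychometric validation and subscale scoring for ordinal
    questionnaires measuring responsiveness and respectful treatment in
    maternity care. Implements the full pipeline: declarative
    questionnaire schemas with recode and reverse-coding rules,
    respondent screening and median imputation, polychoric correlation
    estimation with sampling-adequacy diagnostics (Bartlett's sphericity
    test, Kaiser-Meyer-Olkin), Horn's parallel analysis, principal-axis
    factoring with Promax rotation, McDonald's omega, an iterative
    factor-solution acceptance search with item elimination, confirmatory
    factor analysis by diagonally weighted least squares with
    CFI/TLI/RMSEA/SRMR fit indices, and two subscale scoring methods
    (unweighted sum scores and loading-weighted factor scores on a 0-10
    scale) with domain and overall percentage aggregation. Ships a
    synthetic-cohort generator with a six-factor thresholded-Gaussian
    ordinal model so every stage is testable without access to restricted
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
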