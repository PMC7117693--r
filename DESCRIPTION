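Package: epicesdif
Title: Differential Item Functioning Analysis of the EPICES Deprivation Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An item-response-theory workflow for the 11-item binary EPICES
    social-deprivation questionnaire: marginal-maximum-likelihood fitting of the
    graded response model (two-parameter logistic for binary items), EAP latent
    trait scoring, item-fit and local-independence diagnostics (infit/outfit,
    residual PCA, residual Spearman correlations), hybrid ordinal logistic
    regression detection and classification of uniform and non-uniform
    differential item functioning with McFadden pseudo-R2 magnitude bands,
    impact assessment through latent-score correlations, and classical
    psychometrics (Cronbach's alpha, chi-square endorsement comparisons,
    multiple correspondence analysis with a varimax-type rotation). A synthetic
    cohort generator with controllable DIF, group impact and a locally
    dependent item pair makes every stage testable without individual-level
    study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
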