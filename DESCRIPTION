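Package: immunocompare
Title: Comparative Immunogenomic Analysis of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing the immunogenomic landscape of two
    tumor cohorts of unequal size, for example a cancer-of-unknown-primary (CUP)
    cohort against a mixed metastatic reference cohort. Covers variance-based
    gene selection and rank-based differential expression on log2 TPM values,
    hypergeometric over-representation analysis, single-sample pathway scoring
    by gene set variation analysis (GSVA), marker-gene tumor-infiltrating
    leukocyte (TIL) scores, a rule-based cancer driver annotation engine, tumor
    mutation burden (TMB), the weighted genome integrity index (wGII), and
    single-base-substitution mutational signature refitting. A synthetic
    two-cohort generator reproduces the statistical structure the analysis
    assumes, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    uwot
Config/testthat/edition: 3
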