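Package: promark
Title: Biomarker Discovery for Matched Biofluid Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end label-free quantitative proteomics analysis
    pipeline for matched case-control biofluid cohorts (cerebrospinal
    fluid and plasma). Implements left-censored downshift imputation,
    per-protein two-group testing with permutation-based false discovery
    rates, cross-fluid permutation correlation tests, correlation-pruned
    panel selection, repeated cross-validated comparison of diagnostic
    classifiers, exhaustive best-subset prognostic regression, stable
    isotope label normalized targeted peptide group comparison, and
    hypergeometric pathway over-representation with an empirical
    background. Includes a matched-cohort simulator with known ground
    truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    kernlab,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
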