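Package: seroscreen
Title: Autoantibody Screening Analysis for Antigen Protein Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serological screening of tumor-associated
    antigens on self-assembled (NAPPA-style) protein microarrays. Reads
    GenePix-dialect spot quantification tables, performs control-spot based
    normalization (nonspot first-quartile background correction and
    empty-vector median scaling), calls seropositive autoantibody reactivities
    with an empty-vector mean + 3SD rule, derives a differential immunome of
    tumor-associated antigens by Mann-Whitney testing with positivity and
    fold-change gates, selects metastasis-discriminating marker panels by a
    balanced leave-one-out LASSO voting procedure, and evaluates panels with
    ROC curves and Ward clustering. Includes a synthetic-cohort generator with
    planted differential antigens so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    jsonlite
Config/testthat/edition: 3
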