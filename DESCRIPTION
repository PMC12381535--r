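Package: dergar
Title: Greedy Backward Feature Elimination for Survival-Status
    Classification After Allogeneic Stem Cell Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Data Ensemble Refinement Greedy Algorithm
    (DERGA), a wrapper-style backward feature-elimination procedure for
    multiclass classification of clinical tabular data, applied to
    survival-status prediction in adult recipients of allogeneic
    haematopoietic stem cell transplantation (allo-HSCT).  Provides a
    cohort data model for the 18 pre- and post-transplant parameters, a
    synthetic cohort generator with configurable planted outcome
    signals, five tree-based classification meta-algorithms evaluated
    under a repeated random split-and-seed protocol, pattern-count
    accounting, optimal-pattern selection, parameter influence ranking,
    and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
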