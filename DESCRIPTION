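Package: posticu
Title: Post-ICU Discharge Deterioration Prediction from Irregular Clinical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts unplanned ICU readmission or death within seven days of
    ICU-to-ward transfer from daily-gridded, heavily missing clinical time
    series. Implements gated recurrent classifiers with trainable decay-based
    imputation (GRU-D and an extension handling channels with no prior
    observation in the stay), the SWIFT discharge score as a clinical
    comparator, cohort selection and endpoint labeling rules, stratified
    cross-validated evaluation with paired DeLong AUROC comparison and
    fine-tuning curves, permutation-sampling Shapley feature attribution, and
    a seeded synthetic ICU-stay generator so the full pipeline is exercisable
    without credentialed electronic health record data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    ranger,
    xgboost,
    pROC
Config/testthat/edition: 3
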