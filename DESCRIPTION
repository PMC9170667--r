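Package: clockbias
Title: Bias Evaluation for DNA Methylation Age Predictors in Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying systematic bias when an
    epigenetic age predictor trained on healthy children is applied to a
    clinical target cohort such as children with growth disorders. Provides a
    percent-methylation cohort container with CSV interchange, a synthetic
    cohort simulator with known per-CpG age trajectories and disease shifts,
    Spearman-based clock-CpG selection and ANCOVA robustness screening, a
    bagged regression-forest age model with curvature-test split selection and
    surrogate splits for missing values, age- and sex-matched paired test
    subsampling, and aggregation of mean absolute errors and age gaps across
    repeated matched runs.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
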