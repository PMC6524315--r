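Package: ctpirp
Title: Risk-Group Stratification and Temporal Validation for Chronic Kidney Disease Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CT-PIRP classification-tree stratification of
    chronic kidney disease patients into seven prognostic subgroups and the
    survival machinery needed to validate such a risk-group model on a later
    enrolment wave of the same registry: Kaplan-Meier estimation with delayed
    entry, cause-specific Cox models with cluster-robust variance, calibration
    by baseline-survival transfer, Fine-Gray subdistribution-hazard models and
    cumulative incidence functions, 1:1 cohort matching on node membership and
    follow-up duration, descriptive cohort-comparison statistics, and a
    synthetic competing-risks cohort generator for testing every pipeline
    stage without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    survival,
    stats,
    utils,
    readr,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
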