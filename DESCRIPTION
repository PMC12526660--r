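Package: hrvpipe
Title: Heart Rate Variability Typicality Pipelines for Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw single-lead electrocardiogram (ECG)
    recordings into age-adjusted heart rate variability (HRV) typicality
    targets and benchmarking regression models on them. Includes a synthetic
    ECG cohort generator with ground-truth R-peak times, a Pan-Tompkins style
    R-peak detector, time-domain HRV features (RMSSD, mean heart rate, R-peak
    count), an age-stratified probabilistic typicality score built from
    normative RMSSD reference ranges, a preprocessing pipeline (percentile
    winsorization, Spearman collinearity screening with synthetic-feature
    construction, standardization), and a model benchmark with
    Gaussian-process hyperparameter optimization, cross-validation, and a
    federated per-site variant. All stages take and return tibbles and
    compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    lhs,
    purrr,
    ranger,
    readr,
    rlang (>= 1.0.0),
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
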