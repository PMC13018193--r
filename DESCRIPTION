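Package: phenowear
Title: Digital Phenotyping of Wearable Activity, Heart-Rate and Sleep Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for smartphone and smartwatch digital phenotyping of
    idiopathic pulmonary arterial hypertension (IPAH) risk. Provides a
    seed-reproducible synthetic cohort generator calibrated to published
    group-level activity, heart-rate and sleep statistics; cleaning of
    HealthKit-style records (exact-duplicate removal, daily-plausibility
    outlier bounds, invalid-row handling); derived gait and cardiac metrics
    (interval paces, heart-rate reserve, cardiac effort, bed-bound flag,
    time above 70 percent of maximum pace); group comparisons and temporal
    profiling with FDR control; monthly time-, frequency-domain and
    autoregressive featurization; participant-level cross-validated
    gradient-boosted-tree and linear SVM classifiers; Population Stability
    Index drift monitoring; and a transfer-learning mix-in protocol for
    external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    jsonlite,
    yaml,
    stats,
    utils,
    xgboost,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
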