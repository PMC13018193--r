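# Featurization: monthly aggregation, the 26-feature set against brute-force
# oracles, spectral identities, AR recovery, questionnaire encoding, and
# feature-matrix assembly.

test_that("monthly aggregation takes calendar-month means and keeps gaps", {
  d <- tibble::tibble(
    participant_id = "P1", device = "phone", variable = "stepCount",
    date = as.Date(c("2021-01-05", "2021-01-20", "2021-03-10")),
    value = c(10, 20, 50)
  )
  m <- monthly_aggregate(d)
  expect_identical(nrow(m), 2L)
  expect_equal(m$value[m$month == as.Date("2021-01-01")], 15)
  expect_false(as.Date("2021-02-01") %in% m$month)
  same <- monthly_aggregate(tibble::tibble(
    participant_id = "P1", device = "phone", variable = "x",
    date = as.Date("2021-01-01") + 0:29, value = 7
  ))
  expect_equal(same$value, 7)
})

test_that("time-domain features match the worked example", {
  f <- time_domain_features(c(1, 2, 3))
  expect_equal(f[["MEAN"]], 2)
  expect_equal(f[["P2P"]], 2)
  expect_equal(f[["VAR"]], 1)
  expect_equal(f[["RMS"]], sqrt(14 / 3))
  expect_equal(f[["CREST_FACTOR"]], 3 / sqrt(14 / 3))
  expect_equal(f[["cc_lag0"]], 1)
})

test_that("degenerate series yield missing, not fabricated, features", {
  const <- time_domain_features(rep(5, 10))
  expect_equal(const[["VAR"]], 0)
  expect_equal(const[["P2P"]], 0)
  expect_true(is.na(const[["cc_lag1"]]))
  expect_true(is.na(const[["SKEW"]]))
  short <- time_domain_features(c(1, 2))
  expect_true(is.na(short[["SKEW"]]))
  expect_true(is.na(short[["KURTOSIS"]]))
  expect_equal(short[["N"]], 2)
  ff <- freq_domain_features(c(1, 2, 3))
  expect_true(all(is.na(ff)))
})

test_that("time-domain features agree with the brute-force oracle", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:36, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 50))
    got <- time_domain_features(x)
    want <- oracle_time_features(x)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10, label = nm)
    }
  }
})

test_that("spectral features agree with a direct DFT oracle", {
  set.seed(321)
  for (i in 1:50) {
    n <- sample(4:24, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 10))
    got <- freq_domain_features(x)
    want <- oracle_freq_features(x)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-8, label = nm)
    }
  }
})

test_that("a pure cosine concentrates its spectrum in one bin pair", {
  n <- 24
  x <- cos(2 * pi * 3 * (0:(n - 1)) / n)
  f <- freq_domain_features(x)
  # bins k = 3 and k = n - 3 carry all mass, each n/2
  expect_equal(f[["MAX_f"]], n / 2, tolerance = 1e-8)
  expect_equal(f[["SUM_f"]], n, tolerance = 1e-8)
  const <- freq_domain_features(rep(2, 12))
  expect_equal(const[["SUM_f"]], 0)
  expect_equal(const[["POWER"]], 0)
})

test_that("POWER equals the sample variance (Parseval identity)", {
  set.seed(777)
  for (i in 1:50) {
    x <- rnorm(sample(4:40, 1), sd = runif(1, 0.1, 20))
    f <- freq_domain_features(x)
    expect_equal(f[["POWER"]], var(x), tolerance = 1e-10)
  }
})

test_that("AR(2) parameters are recovered within 2 SE at N = 200", {
  set.seed(2718)
  phi <- c(0.5, -0.3)
  x <- as.numeric(arima.sim(list(ar = phi), n = 200, sd = 1))
  f <- ar_features(x)
  se <- sqrt((1 - phi[2]^2) / 200)
  expect_lt(abs(f[["ar.L1"]] - phi[1]), 2 * se)
  expect_lt(abs(f[["ar.L2"]] - phi[2]), 2 * se)
  expect_lt(abs(f[["sigma2"]] - 1), 2 * sqrt(2 / 200))
})

test_that("white noise gives near-zero AR coefficients; short series none", {
  set.seed(10)
  x <- rnorm(300)
  f <- ar_features(x)
  expect_lt(abs(f[["ar.L1"]]), 0.15)
  expect_lt(abs(f[["ar.L2"]]), 0.15)
  expect_true(all(is.na(ar_features(rnorm(5)))))
})

test_that("spectral and AR features use the longest contiguous run", {
  x <- c(1, 2, NA, 5, 6, 7, 8, 9, 10, 11, 12, 13)
  run <- phenowear:::longest_run(x)
  expect_identical(run, c(5, 6, 7, 8, 9, 10, 11, 12, 13))
  f <- freq_domain_features(x)
  expect_equal(f[["POWER"]], var(run), tolerance = 1e-10)
})

test_that("questionnaire encoding maps scales and keeps missing missing", {
  resp <- tibble::tibble(
    participant_id = c("A", "A", "B"),
    survey_block = c("Mindset", "PARQ", "Mindset"),
    item_id = c("exercise_easy", "parq_q1", "exercise_easy"),
    response = c(4L, 1L, 2L)
  )
  enc <- encode_questionnaires(resp)
  expect_equal(enc$Mindset__exercise_easy, c(4, 2))
  expect_equal(enc$PARQ__parq_q1, c(1, NA))
  only_mind <- encode_questionnaires(resp, blocks = "Mindset")
  expect_identical(names(only_mind), c("participant_id", "Mindset__exercise_easy"))
  # full block for one participant: one feature per item
  sc <- shared_record_cohort()
  one <- sc$cohort$questionnaires |>
    dplyr::filter(.data$survey_block == "Mindset")
  encm <- encode_questionnaires(one, blocks = "Mindset")
  expect_lte(ncol(encm) - 1L, 7L)
})

test_that("feature matrix has one row per participant and stable naming", {
  fx <- shared_model_features()
  fm <- fx$fm_uk
  expect_identical(anyDuplicated(fm$x$participant_id), 0L)
  expect_true(all(grepl("^[A-Za-z]+__(phone|watch)__", fm$feature_cols)))
  expect_identical(length(fm$label), nrow(fm$x))
  expect_true(all(fm$label %in% c(0L, 1L)))
  # 26 features per (variable, device) series
  vars <- unique(sub("__.*$", "", fm$feature_cols))
  expect_identical(length(fm$feature_cols), length(vars) * 26L)
})

test_that("phase filtering drops post-diagnosis months for cases only", {
  fx <- shared_model_features()
  uk <- fx$uk
  fm_pre <- fx$fm_uk
  fm_all <- build_feature_matrix(uk$daily, uk$participants,
                                 phase = "all", device = "phone")
  n_col <- paste0("stepCount__phone__N")
  ipah <- names(fm_pre$label[fm_pre$label == 1])
  ctrl <- names(fm_pre$label[fm_pre$label == 0])
  pre_n <- fm_pre$x[[n_col]][match(ipah, fm_pre$x$participant_id)]
  all_n <- fm_all$x[[n_col]][match(ipah, fm_all$x$participant_id)]
  expect_true(all(pre_n <= all_n, na.rm = TRUE))
  expect_lt(mean(pre_n, na.rm = TRUE), mean(all_n, na.rm = TRUE))
  # controls contribute the same months in both analyses
  pre_c <- fm_pre$x[[n_col]][match(ctrl, fm_pre$x$participant_id)]
  all_c <- fm_all$x[[n_col]][match(ctrl, fm_all$x$participant_id)]
  expect_equal(pre_c, all_c)
})

test_that("questionnaire blocks append to the activity matrix", {
  fx <- shared_model_features()
  uk <- fx$uk
  fm_q <- build_feature_matrix(uk$daily, uk$participants,
                               responses = uk$questionnaires,
                               blocks = "Mindset", phase = "pre",
                               device = "phone")
  expect_true(any(grepl("^Mindset__", fm_q$feature_cols)))
  expect_identical(
    setdiff(fm_q$feature_cols, fx$fm_uk$feature_cols),
    grep("^Mindset__", fm_q$feature_cols, value = TRUE)
  )
})
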