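# Synthetic cohort generator: validation, determinism, schema, group-effect
# directions, modulation and drift behaviour.

test_that("configuration invariants are enforced", {
  expect_s3_class(generator_config(), "pw_config")
  expect_error(generator_config(duplicate_rate = 1.2), class = "phenowear_config_error")
  expect_error(generator_config(date_span = 0), class = "phenowear_config_error")
  expect_error(generator_config(missingness = list(short_gap = -0.1, long_gap = 0)),
               class = "phenowear_config_error")
  bad <- default_group_params()
  bad$p2[5] <- -1
  expect_error(generator_config(group_params = bad), class = "phenowear_config_error")
})

test_that("identical (config, seed) pairs give byte-identical output", {
  cfg <- generator_config(n_per_group = c(IPAH = 3L, DC = 2L, Healthy = 4L),
                          date_span = 40L, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$records, b$records)
  expect_identical(a$questionnaires, b$questionnaires)
})

test_that("different seeds change values but preserve schema and scale", {
  cfg1 <- generator_config(n_per_group = c(IPAH = 3L, DC = 2L, Healthy = 4L),
                           date_span = 60L, seed = 1L)
  cfg2 <- generator_config(n_per_group = c(IPAH = 3L, DC = 2L, Healthy = 4L),
                           date_span = 60L, seed = 2L)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg2)
  expect_false(identical(a$records$value, b$records$value))
  expect_identical(names(a$records), names(b$records))
  # row counts agree in expectation; allow generous sampling slack
  expect_lt(abs(nrow(a$records) - nrow(b$records)) / nrow(a$records), 0.1)
})

test_that("roster respects the group structure and diagnosis-date rule", {
  sc <- shared_record_cohort()
  p <- sc$cohort$participants
  expect_identical(sum(p$group == "IPAH"),
                   unname(sc$config$n_per_group[["IPAH"]]))
  expect_true(all(!is.na(p$diagnosis_date[p$group == "IPAH"])))
  expect_true(all(is.na(p$diagnosis_date[p$group != "IPAH"])))
  expect_true(all(p$region == "UK"))
})

test_that("contamination labels are internal and rates are honoured", {
  sc <- shared_record_cohort()
  r <- sc$cohort$records
  expect_true(all(c("none", "duplicate", "outlier", "invalid") %in% unique(r$injected)))
  dup_share <- mean(r$injected == "duplicate")
  expect_equal(dup_share, sc$config$duplicate_rate, tolerance = 0.01)
})

test_that("zero contamination means the cleaning chain removes nothing", {
  cfg <- generator_config(n_per_group = c(IPAH = 2L, DC = 2L, Healthy = 2L),
                          date_span = 30L, duplicate_rate = 0, outlier_rate = 0,
                          invalid_rate = 0, seed = 3L)
  co <- generate_cohort(cfg)
  cl <- clean_records(co$records)
  expect_identical(unname(cl$removed), c(0L, 0L, 0L))
  expect_identical(nrow(cl$records), nrow(co$records))
})

test_that("turning off modulation recovers the configured medians", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 10L, DC = 5L, Healthy = 20L), date_span = 200L,
    weekend_effect = c(IPAH = 1, DC = 1, Healthy = 1), seasonal_amplitude = 0,
    missingness = list(short_gap = 0, long_gap = 0), seed = 8L
  )
  co <- generate_cohort(cfg, output = "daily")
  d <- co$daily
  hp <- d$value[d$group == "Healthy" & d$device == "phone" & d$variable == "stepCount"]
  expect_equal(median(hp), 4620, tolerance = 0.05)
  hw <- d$value[d$group == "Healthy" & d$device == "watch" & d$variable == "restingHeartRate"]
  expect_equal(median(hw), 62, tolerance = 0.02)
})

test_that("group-effect directions match the calibrated sign pattern", {
  cfg <- generator_config(n_per_group = c(IPAH = 30L, DC = 30L, Healthy = 30L),
                          date_span = 120L, seed = 21L)
  co <- generate_cohort(cfg, output = "daily")
  d <- co$daily
  med <- function(var, grp, dev) {
    median(d$value[d$variable == var & d$group == grp & d$device == dev])
  }
  lower_in_ipah <- c("stepCount", "flightsClimbed", "StepCountPaceMax",
                     "FlightsClimbedPaceMax")
  for (v in lower_in_ipah) {
    expect_lt(med(v, "IPAH", "phone"), med(v, "Healthy", "phone"))
  }
  expect_lt(med("heartRateVariabilitySDNN", "IPAH", "watch"),
            med("heartRateVariabilitySDNN", "Healthy", "watch"))
  expect_lt(med("VO2Max", "IPAH", "watch"), med("VO2Max", "Healthy", "watch"))
  expect_gt(med("walkingHeartRate", "IPAH", "watch"),
            med("walkingHeartRate", "Healthy", "watch"))
  expect_gt(med("Awake", "IPAH", "watch"), med("Awake", "Healthy", "watch"))
  # and the separation is statistically clear at n = 30/group
  part_med <- d |>
    dplyr::filter(.data$variable == "stepCount", .data$device == "phone",
                  .data$group %in% c("IPAH", "Healthy")) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(value = median(.data$value), .groups = "drop")
  p <- wilcox.test(value ~ group, data = part_med, exact = FALSE)$p.value
  expect_lt(p, 0.05)
})

test_that("US drift scales lognormal medians analytically", {
  drift <- default_region_drift()
  cfg <- generator_config(
    n_per_group = c(IPAH = 8L, DC = 4L, Healthy = 16L), date_span = 150L,
    weekend_effect = c(IPAH = 1, DC = 1, Healthy = 1), seasonal_amplitude = 0,
    region_drift = c(stepCount = 0.5), seed = 13L
  )
  us <- generate_us_cohort(cfg, output = "daily")
  d <- us$daily
  hp <- d$value[d$group == "Healthy" & d$device == "phone" & d$variable == "stepCount"]
  # lognormal median scales exactly with the multiplier
  expect_equal(median(hp), 4620 * 0.5, tolerance = 0.06)
  expect_true(all(d$value[d$variable == "stepCount"] >= 0))
  expect_equal(unname(drift[["StepCountPaceMax"]]), 86 / 112)
})

test_that("identity drift leaves UK and US distributions indistinguishable", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 6L, DC = 3L, Healthy = 12L), date_span = 120L,
    region_drift = c(stepCount = 1), seed = 17L
  )
  uk <- generate_cohort(cfg, output = "daily")
  us <- generate_us_cohort(cfg, output = "daily")
  a <- uk$daily$value[uk$daily$variable == "stepCount" & uk$daily$device == "phone"]
  b <- us$daily$value[us$daily$variable == "stepCount" & us$daily$device == "phone"]
  expect_lt(psi(a, b)$psi, 0.05)
})

test_that("long gaps drop whole calendar months", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 2L, DC = 2L, Healthy = 2L), date_span = 365L,
    missingness = list(short_gap = 0, long_gap = 0.5), seed = 19L
  )
  co <- generate_cohort(cfg, output = "daily")
  mo <- co$daily |>
    dplyr::mutate(month = format(date, "%Y-%m")) |>
    dplyr::distinct(.data$participant_id, .data$date, .data$month) |>
    dplyr::count(.data$participant_id, .data$month)
  # surviving months are complete runs of days (no partially-missing months)
  spans <- co$daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_months = dplyr::n_distinct(format(date, "%Y-%m")))
  expect_lt(mean(spans$n_months), 13)
  expect_gt(nrow(mo), 0)
})
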