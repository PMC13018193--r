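# Group comparison layer: rank tests with FDR control, temporal profiles,
# pre/post-diagnosis contrast.

fake_daily <- function(n_per_group, n_days, shift = 0, seed = 1) {
  set.seed(seed)
  groups <- rep(c("IPAH", "Healthy"), c(n_per_group, n_per_group))
  ids <- sprintf("S%03d", seq_along(groups))
  d <- tidyr::crossing(participant_id = ids,
                       date = as.Date("2021-01-01") + 0:(n_days - 1))
  d$device <- "phone"
  d$variable <- "metric"
  mu <- ifelse(rep(groups, each = n_days) == "IPAH", -shift, 0)
  d$value <- rnorm(nrow(d), mu, 1)
  roster <- tibble::tibble(id = ids, group = groups,
                           age_at_consent = 50, sex = "F", bmi = 25,
                           ethnicity = "White")
  list(daily = d, roster = roster)
}

test_that("null comparison yields non-significant adjusted p-values", {
  fx <- fake_daily(30, 20, shift = 0, seed = 5)
  res <- compare_groups(fx$daily, fx$roster)
  expect_identical(nrow(res), 1L)
  expect_gt(res$p_IPAH_vs_Healthy, 0.01)
  expect_true(is.na(res$p_IPAH_vs_DC))  # no DC group present
  expect_identical(res$n_IPAH, 30L)
})

test_that("a one-SD location shift is detected with high power", {
  hits <- 0
  for (s in 1:5) {
    fx <- fake_daily(50, 10, shift = 1, seed = s)
    res <- compare_groups(fx$daily, fx$roster)
    if (res$p_adj_IPAH_vs_Healthy < 0.05) hits <- hits + 1
    expect_lt(res$median_IPAH, res$median_Healthy)
  }
  expect_gte(hits, 5)
})

test_that("null battery keeps type-I error near nominal and BH is monotone", {
  set.seed(99)
  n <- 30
  ids <- sprintf("S%03d", 1:(2 * n))
  groups <- rep(c("IPAH", "Healthy"), each = n)
  vars <- sprintf("v%02d", 1:40)
  d <- tidyr::crossing(participant_id = ids, variable = vars,
                       date = as.Date("2021-01-01") + 0:4)
  d$device <- "phone"
  d$value <- rnorm(nrow(d))
  roster <- tibble::tibble(id = ids, group = groups)
  res <- compare_groups(d, roster)
  frac <- mean(res$p_IPAH_vs_Healthy < 0.05)
  expect_lt(frac, 0.15)                       # near the nominal 5%
  expect_true(all(res$p_adj_IPAH_vs_Healthy >= res$p_IPAH_vs_Healthy - 1e-12))
  ord_raw <- order(res$p_IPAH_vs_Healthy)
  expect_true(!is.unsorted(res$p_adj_IPAH_vs_Healthy[ord_raw]))
})

test_that("small groups are skipped with a warning", {
  fx <- fake_daily(30, 5, seed = 3)
  fx$roster$group[fx$roster$group == "IPAH"] <- c("IPAH", "IPAH",
                                                  rep("DC", 28))
  fx2 <- fx
  expect_warning(res <- compare_groups(fx2$daily, fx2$roster), "skipped")
  expect_identical(nrow(res), 0L)
})

test_that("covariate adjustment preserves a true group effect", {
  fx <- fake_daily(40, 10, shift = 1.2, seed = 11)
  res <- compare_groups(fx$daily, fx$roster, adjust_covariates = TRUE)
  expect_lt(res$p_adj_IPAH_vs_Healthy, 0.05)
})

test_that("weekday profile recovers the configured weekend contrast", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 4L, DC = 2L, Healthy = 30L), date_span = 365L,
    weekend_effect = c(IPAH = 1, DC = 1, Healthy = 0.8),
    seasonal_amplitude = 0, seed = 23L
  )
  co <- generate_cohort(cfg, output = "daily")
  d <- co$daily |> dplyr::filter(.data$variable == "stepCount",
                                 .data$device == "phone")
  prof <- temporal_profile(d, co$participants, axis = "weekday")
  h <- prof[prof$group == "Healthy", ]
  weekend <- mean(h$mean[h$bin %in% c(6, 7)])
  weekday <- mean(h$mean[h$bin %in% 1:5])
  expect_equal(weekend / weekday, 0.8, tolerance = 0.08)
})

test_that("month profile recovers the seasonal phase", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 2L, DC = 2L, Healthy = 20L), date_span = 365L,
    weekend_effect = c(IPAH = 1, DC = 1, Healthy = 1),
    seasonal_amplitude = 0.4, seed = 29L
  )
  co <- generate_cohort(cfg, output = "daily")
  d <- co$daily |> dplyr::filter(.data$variable == "stepCount",
                                 .data$device == "phone")
  prof <- temporal_profile(d, co$participants, axis = "month")
  h <- prof[prof$group == "Healthy", ]
  expect_true(h$bin[which.max(h$mean)] %in% 6:8)   # summer peak
  expect_true(h$bin[which.min(h$mean)] %in% c(11, 12, 1, 2))  # winter trough
})

test_that("hourly profile reflects the circadian allocation of steps", {
  sc <- shared_clean_daily()
  rec <- sc$cleaned$records
  hourly <- aggregate_records(rec[rec$variable == "stepCount", ], "hourly")
  prof <- temporal_profile(hourly, sc$participants, axis = "hour")
  h <- prof[prof$group == "Healthy", ]
  expect_gt(mean(h$mean[h$bin %in% 9:18]), mean(h$mean[h$bin %in% c(0:5)]))
})

test_that("pre/post contrast detects the configured recovery and respects nulls", {
  cfg <- generator_config(
    n_per_group = c(IPAH = 20L, DC = 2L, Healthy = 2L), date_span = 420L,
    prepost_effect = list(activity = 1.3, heart = 0.95),
    variables = c("stepCount", "restingHeartRate"), seed = 31L
  )
  co <- generate_cohort(cfg, output = "daily")
  res <- pre_post_change(co$daily, co$participants)
  step <- res[res$variable == "stepCount", ]
  expect_lt(step$p_value, 0.05)
  expect_identical(step$direction, "increase")
  rhr <- res[res$variable == "restingHeartRate", ]
  expect_identical(rhr$direction, "decrease")

  cfg0 <- generator_config(
    n_per_group = c(IPAH = 15L, DC = 2L, Healthy = 2L), date_span = 420L,
    prepost_effect = list(activity = 1.0, heart = 1.0),
    variables = c("stepCount"), seed = 37L
  )
  co0 <- generate_cohort(cfg0, output = "daily")
  res0 <- pre_post_change(co0$daily, co0$participants)
  expect_gt(res0$p_value[res0$variable == "stepCount"], 0.01)
})

test_that("degenerate single-participant input is handled", {
  roster <- tibble::tibble(id = "A", group = "IPAH",
                           diagnosis_date = as.Date("2021-06-01"))
  daily <- tibble::tibble(participant_id = "A",
                          date = as.Date("2021-05-30") + 0:3,
                          device = "phone", variable = "stepCount",
                          value = c(1, 2, 3, 4))
  res <- pre_post_change(daily, roster)
  expect_true(is.na(res$p_value))
  expect_identical(res$n_participants, 1L)
})
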