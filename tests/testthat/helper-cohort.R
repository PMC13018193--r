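# Shared fixtures, generated once per test run and cached. Problem sizes are
# kept modest: group proportions mirror the default roster so pooled
# statistics are comparable to the full-scale defaults.

.pw_test_cache <- new.env(parent = emptyenv())

shared_record_cohort <- function() {
  if (is.null(.pw_test_cache$rec)) {
    cfg <- generator_config(
      n_per_group = c(IPAH = 18L, DC = 9L, Healthy = 36L),
      date_span = 300L, seed = 2024L
    )
    .pw_test_cache$rec <- list(config = cfg, cohort = generate_cohort(cfg))
  }
  .pw_test_cache$rec
}

shared_clean_daily <- function() {
  if (is.null(.pw_test_cache$daily)) {
    sc <- shared_record_cohort()
    cl <- clean_records(sc$cohort$records)
    daily <- aggregate_records(cl$records, "daily")
    metrics <- derive_daily_metrics(cl$records, daily)
    .pw_test_cache$daily <- list(
      cleaned = cl,
      daily = tag_diagnosis_phase(daily, sc$cohort$participants),
      metrics = tag_diagnosis_phase(metrics, sc$cohort$participants),
      participants = sc$cohort$participants
    )
  }
  .pw_test_cache$daily
}

# small day-level cohorts for modelling tests
shared_model_features <- function() {
  if (is.null(.pw_test_cache$fm)) {
    cfg <- generator_config(
      n_per_group = c(IPAH = 15L, DC = 8L, Healthy = 25L),
      date_span = 540L, seed = 77L
    )
    uk <- generate_cohort(cfg, output = "daily")
    us <- generate_us_cohort(cfg, output = "daily")
    .pw_test_cache$fm <- list(
      uk = uk, us = us,
      fm_uk = build_feature_matrix(uk$daily, uk$participants,
                                   phase = "pre", device = "phone"),
      fm_us = build_feature_matrix(us$daily, us$participants,
                                   phase = "pre", device = "phone")
    )
  }
  .pw_test_cache$fm
}

# tiny hand-rolled record table for cleaning/aggregation unit tests
tiny_records <- function() {
  mk <- function(pid, var, val, start, end, dev = "phone") {
    tibble::tibble(
      participant_id = pid, variable = var, value = val, unit = "u",
      start_time = as.POSIXct(start, tz = "UTC"),
      end_time = as.POSIXct(end, tz = "UTC"),
      device = dev, region = "UK"
    )
  }
  dplyr::bind_rows(
    mk("P1", "stepCount", 100, "2021-06-01 09:00:00", "2021-06-01 09:10:00"),
    mk("P1", "stepCount", 200, "2021-06-01 15:00:00", "2021-06-01 15:20:00"),
    mk("P1", "restingHeartRate", 60, "2021-06-01 08:00:00", "2021-06-01 08:01:00", "watch"),
    mk("P1", "averageHeartRate", 60, "2021-06-02 10:00:00", "2021-06-02 10:01:00", "watch"),
    mk("P1", "averageHeartRate", 80, "2021-06-02 14:00:00", "2021-06-02 14:01:00", "watch"),
    mk("P2", "stepCount", 500, "2021-06-01 12:00:00", "2021-06-01 12:30:00")
  )
}
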