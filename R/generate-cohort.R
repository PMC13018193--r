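#' Generate a synthetic wearable cohort
#'
#' Draws a seed-reproducible cohort of participants (IPAH, disease control,
#' healthy), their raw phone/watch record streams, and questionnaire
#' responses, with the statistical structure the package is designed to
#' analyse: group-specific daily distributions, diurnal/weekly/seasonal
#' modulation, a post-diagnosis recovery effect in IPAH, device provenance,
#' and injected contamination (exact duplicates, out-of-bounds outliers,
#' invalid rows, short and month-long gaps). Contaminated rows are labelled
#' in the `injected` column so cleaning recall/precision can be computed
#' exactly; the label is ignored by every cleaning operation.
#'
#' With `output = "daily"` the generator returns the clean day-level truth
#' (no record expansion, no contamination); useful for fast downstream
#' modelling experiments.
#'
#' @param config A [generator_config()] object.
#' @param output `"records"` (default) for raw record streams, `"daily"` for
#'   the clean day-level table.
#' @param region Cohort region label; use [generate_us_cohort()] for the
#'   drifted external cohort.
#' @return A list of class `pw_cohort` with elements `participants`,
#'   `records` (or `daily`), and `questionnaires`.
#' @export
generate_cohort <- function(config = generator_config(),
                            output = c("records", "daily"),
                            region = "UK") {
  validate_config(config)
  output <- match.arg(output)
  with_seed(derive_seed(config$seed, paste0("cohort-", region)), {
    participants <- make_roster(config, region)
    daily <- sample_daily_truth(participants, config, region)
    if (output == "daily") {
      res <- list(participants = participants, daily = daily,
                  questionnaires = generate_questionnaires(participants, config))
      return(structure(res, class = "pw_cohort"))
    }
    records <- expand_records(daily, config)
    records <- contaminate_records(records, config)
    res <- list(participants = participants, records = records,
                questionnaires = generate_questionnaires(participants, config))
    structure(res, class = "pw_cohort")
  })
}

#' Generate the drifted external (US) cohort
#'
#' Identical pipeline to [generate_cohort()] with the configured per-variable
#' `region_drift` multipliers applied to the distribution locations, so the
#' direction of the IPAH-vs-control differences is conserved while their
#' scale shifts.
#'
#' @inheritParams generate_cohort
#' @return A `pw_cohort` list with `region = "US"` on every record.
#' @export
generate_us_cohort <- function(config = generator_config(),
                               output = c("records", "daily")) {
  generate_cohort(config, output = match.arg(output), region = "US")
}

#' @export
print.pw_cohort <- function(x, ...) {
  cat("<phenowear synthetic cohort>\n")
  cat("  participants: ", nrow(x$participants), " (",
      paste(sprintf("%s=%d", names(table(x$participants$group)),
                    as.integer(table(x$participants$group))), collapse = ", "),
      ")\n", sep = "")
  if (!is.null(x$records)) cat("  records:      ", nrow(x$records), "\n", sep = "")
  if (!is.null(x$daily)) cat("  daily rows:   ", nrow(x$daily), "\n", sep = "")
  cat("  questionnaire responses: ", nrow(x$questionnaires), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# roster

make_roster <- function(config, region) {
  n <- config$n_per_group
  groups <- rep(c("IPAH", "DC", "Healthy"), times = n[c("IPAH", "DC", "Healthy")])
  m <- length(groups)
  age_mean <- c(IPAH = 48, DC = 58, Healthy = 45)[groups]
  age_sd <- c(IPAH = 14, DC = 10, Healthy = 12)[groups]
  f_prob <- c(IPAH = 0.76, DC = 0.21, Healthy = 0.67)[groups]
  consent <- config$start_date + sample.int(90L, m, replace = TRUE) - 1L
  span <- config$date_span
  diagnosis <- rep(as.Date(NA), m)
  ipah <- groups == "IPAH"
  # diagnosis sits inside the observation window so both phases carry data
  diagnosis[ipah] <- consent[ipah] +
    round(span * runif(sum(ipah), 0.35, 0.65))
  tibble::tibble(
    id = sprintf("%s%03d", region, seq_len(m)),
    group = groups,
    age_at_consent = round(pmin(pmax(rnorm(m, age_mean, age_sd), 20), 88)),
    sex = ifelse(runif(m) < f_prob, "F", "M"),
    bmi = round(rlnorm(m, log(26), 0.15), 1),
    ethnicity = sample(c("White", "Non-white"), m, replace = TRUE, prob = c(0.85, 0.15)),
    region = region,
    consent_date = consent,
    diagnosis_date = diagnosis,
    has_watch = runif(m) < config$device_split
  )
}

# ---------------------------------------------------------------------------
# day-level truth

weekend_factors <- function(ratio) {
  # weekend/weekday multiplier pair with zero mean on the log scale, so the
  # pooled median is unchanged while the weekend:weekday ratio equals `ratio`
  list(weekend = ratio^(5 / 7), weekday = ratio^(-2 / 7))
}

sample_daily_truth <- function(participants, config, region) {
  span <- config$date_span
  days <- tidyr::crossing(
    participants[, c("id", "group", "consent_date", "diagnosis_date", "has_watch")],
    offset = seq_len(span) - 1L
  ) |>
    mutate(date = .data$consent_date + .data$offset) |>
    select(-"offset")

  # gaps: month-long dropouts then short per-day gaps
  days <- days |>
    mutate(month_key = paste(.data$id, format(.data$date, "%Y-%m")))
  gap_months <- unique(days$month_key)
  gap_months <- gap_months[runif(length(gap_months)) < config$missingness$long_gap]
  days <- days |>
    filter(!(.data$month_key %in% gap_months)) |>
    filter(runif(dplyr::n()) >= config$missingness$short_gap) |>
    select(-"month_key")

  days <- days |>
    mutate(
      post = !is.na(.data$diagnosis_date) & .data$date >= .data$diagnosis_date,
      wknd = lubridate::wday(.data$date) %in% c(1L, 7L),
      doy = lubridate::yday(.data$date)
    )

  params <- config$group_params
  if (!is.null(config$variables)) {
    keep <- config$variables
    if ("stepCount" %in% keep) keep <- c(keep, "StepCountPaceMax")
    if ("flightsClimbed" %in% keep) keep <- c(keep, "FlightsClimbedPaceMax")
    params <- params[params$variable %in% keep, ]
  }
  pace_rows <- grepl("PaceMax$", params$variable)
  params$p1[pace_rows] <- params$p1[pace_rows] * config$pace_calibration
  if (region == "US") {
    drift <- config$region_drift
    hit <- params$variable %in% names(drift)
    params$p1[hit] <- params$p1[hit] * unname(drift[params$variable[hit]])
  }

  grid <- inner_join(params, days, by = "group", relationship = "many-to-many") |>
    filter(.data$device == "phone" | .data$has_watch)

  we <- config$weekend_effect
  wk_ratio <- unname(we[grid$group])
  wk_mult <- ifelse(grid$wknd, wk_ratio^(5 / 7), wk_ratio^(-2 / 7))
  season_mult <- exp(config$seasonal_amplitude *
                       sin(2 * pi * (grid$doy - 105) / 365.25))
  mult <- rep(1, nrow(grid))
  act <- grid$class == "activity"
  mult[act] <- wk_mult[act] * season_mult[act]
  post_ipah <- grid$post & grid$group == "IPAH"
  mult[act & post_ipah] <- mult[act & post_ipah] * config$prepost_effect$activity
  hrt <- grid$class == "heart"
  mult[hrt & post_ipah] <- mult[hrt & post_ipah] * config$prepost_effect$heart

  n <- nrow(grid)
  value <- numeric(n)
  ln <- grid$dist == "lnorm"
  value[ln] <- rlnorm(sum(ln), log(grid$p1[ln] * mult[ln]), grid$p2[ln])
  value[!ln] <- rnorm(sum(!ln), grid$p1[!ln] * mult[!ln], grid$p2[!ln])
  value <- pmin(pmax(value, grid$lo), grid$hi)

  daily <- grid |>
    mutate(value = value, phase = dplyr::case_when(
      is.na(.data$diagnosis_date) ~ "control",
      .data$post ~ "post",
      TRUE ~ "pre"
    )) |>
    select(participant_id = "id", "group", "date", "device", "variable",
           "value", "phase")

  # daily-mode convenience: mean paces derived from the max via the
  # within-day interval profile (see expand_records)
  pace <- daily |>
    filter(grepl("PaceMax$", .data$variable)) |>
    mutate(
      variable = sub("Max$", "Mean", .data$variable),
      value = .data$value * (0.25 + 0.2 * stats::rbeta(dplyr::n(), 2, 2))
    )
  bind_rows(daily, pace) |> arrange(.data$participant_id, .data$date)
}

# ---------------------------------------------------------------------------
# record expansion

expand_records <- function(daily, config) {
  units <- setNames(variable_catalog()$unit, variable_catalog()$variable)
  circ <- config$circadian_profile / sum(config$circadian_profile)

  wide_keys <- c("participant_id", "group", "date", "device", "phase")
  point_vars <- daily |>
    filter(!grepl("^(StepCount|FlightsClimbed)Pace", .data$variable))

  step_days <- build_interval_days(daily, "stepCount", "StepCountPaceMax",
                                   lambda = 6.5, circ = circ)
  flight_days <- build_interval_days(daily, "flightsClimbed", "FlightsClimbedPaceMax",
                                     lambda = 1.5, circ = circ)

  point_recs <- point_vars |>
    filter(!(.data$variable %in% c("stepCount", "flightsClimbed"))) |>
    mutate(
      start_hour = dplyr::case_when(
        .data$variable == "Asleep" ~ 0.25,
        .data$variable == "Awake" ~ 5.0,
        .data$variable %in% c("activeEnergyBurned", "basalEnergyBurned",
                              "appleStandTime", "distanceWalkingRunning") ~ 0.0,
        TRUE ~ runif(dplyr::n(), 8, 21)
      ),
      dur_hours = dplyr::case_when(
        .data$variable %in% c("Asleep", "Awake") ~ .data$value,
        .data$variable %in% c("activeEnergyBurned", "basalEnergyBurned",
                              "appleStandTime", "distanceWalkingRunning") ~ 23.99,
        TRUE ~ 1 / 60
      )
    )

  # bed-time stream derived from the sleep states (for the bed-bound metric)
  sleep_wide <- point_vars |>
    filter(.data$variable %in% c("Asleep", "Awake")) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(wide_keys),
                       names_from = "variable", values_from = "value")
  if (all(c("Asleep", "Awake") %in% names(sleep_wide)) && nrow(sleep_wide) > 0) {
    inbed <- sleep_wide |>
      filter(!is.na(.data$Asleep), !is.na(.data$Awake)) |>
      mutate(variable = "inBed",
             value = pmin(.data$Asleep + .data$Awake + runif(dplyr::n(), 0, 0.5), 23.9),
             start_hour = 0, dur_hours = .data$value) |>
      select(-"Asleep", -"Awake")
    point_recs <- bind_rows(point_recs, inbed)
  }

  to_times <- function(df) {
    start <- as.POSIXct(df$date, tz = "UTC") + round(df$start_hour * 3600)
    df$start_time <- start
    df$end_time <- start + round(df$dur_hours * 3600)
    df
  }
  point_recs <- to_times(point_recs)

  recs <- bind_rows(
    point_recs |> select("participant_id", "variable", "value",
                         "start_time", "end_time", "device"),
    step_days, flight_days
  ) |>
    mutate(unit = unname(units[.data$variable]),
           region = daily_region(daily), injected = "none") |>
    select("participant_id", "variable", "value", "unit",
           "start_time", "end_time", "device", "region", "injected") |>
    arrange(.data$participant_id, .data$start_time, .data$variable)
  recs
}

daily_region <- function(daily) {
  if (any(startsWith(daily$participant_id, "US"))) "US" else "UK"
}

# Split each day's count total D into intervals whose maximum pace equals the
# day's drawn PaceMax; the largest-share interval carries the maximum so its
# duration is never degenerate.
build_interval_days <- function(daily, count_var, pace_var, lambda, circ) {
  d <- daily |>
    filter(.data$variable %in% c(count_var, pace_var)) |>
    tidyr::pivot_wider(
      id_cols = c("participant_id", "date", "device"),
      names_from = "variable", values_from = "value"
    )
  if (!count_var %in% names(d) || nrow(d) == 0) {
    return(tibble::tibble(participant_id = character(), variable = character(),
                          value = numeric(), start_time = as.POSIXct(character(), tz = "UTC"),
                          end_time = as.POSIXct(character(), tz = "UTC"),
                          device = character()))
  }
  d <- d |> filter(!is.na(.data[[count_var]]), !is.na(.data[[pace_var]]))
  D <- pmax(round(d[[count_var]]), 1)
  M <- d[[pace_var]]
  k <- pmin(1L + rpois(nrow(d), lambda), pmax(D, 1L))
  idx <- rep(seq_len(nrow(d)), k)

  n_int <- length(idx)
  hour <- sample.int(24L, n_int, replace = TRUE, prob = circ) - 1L
  w <- stats::rgamma(n_int, shape = 1.2) * circ[hour + 1L]
  day_id <- idx
  wsum <- tapply(w, day_id, sum)[as.character(day_id)]
  share <- w / as.numeric(wsum)
  steps <- floor(D[idx] * share)
  # hand the rounding remainder to the largest interval of each day
  rem <- D - as.numeric(tapply(steps, day_id, sum)[as.character(seq_len(nrow(d)))])
  ord <- order(day_id, -share)
  first_of_day <- ord[!duplicated(day_id[ord])]
  steps[first_of_day] <- steps[first_of_day] + rem[day_id[first_of_day]]

  pace <- runif(n_int, 0.1, 0.4) * M[idx]
  pace[first_of_day] <- M[day_id[first_of_day]]

  keep <- steps > 0
  dur_min <- steps[keep] / pace[keep]
  start <- as.POSIXct(d$date[idx[keep]], tz = "UTC") +
    hour[keep] * 3600 + round(runif(sum(keep), 0, 3599))
  tibble::tibble(
    participant_id = d$participant_id[idx[keep]],
    variable = count_var,
    value = steps[keep],
    start_time = start,
    end_time = start + round(dur_min * 60),
    device = d$device[idx[keep]]
  )
}

# ---------------------------------------------------------------------------
# contamination

# Contamination is injected as EXTRA rows on top of the clean signal, so a
# correct cleaning stage recovers exactly the clean stream: spurious
# out-of-bounds rows (artefactual sensor values), invalid rows (non-finite
# values / pre-epoch dates), and exact duplicate copies. Rates are
# parameterised so that the removal fractions measured downstream equal the
# configured rates: dedup removes duplicate_rate of the emitted stream, the
# bounds filter removes outlier_rate of the post-dedup stream.
contaminate_records <- function(records, config) {
  n0 <- nrow(records)
  bounds <- default_bounds()
  upper <- setNames(bounds$upper, bounds$variable)

  r_out <- config$outlier_rate
  n_out <- round(r_out / (1 - r_out) * n0)
  if (n_out > 0) {
    ii <- sample.int(n0, n_out, replace = n_out > n0)
    outs <- records[ii, ]
    outs$value <- unname(upper[outs$variable]) *
      runif(n_out, 1.05, max(1.1, config$outlier_magnitude))
    outs$injected <- "outlier"
    records <- bind_rows(records, outs)
  }

  r_inv <- config$invalid_rate
  n_inv <- round(r_inv / (1 - r_inv) * nrow(records))
  if (n_inv > 0) {
    ii <- sample.int(n0, n_inv, replace = n_inv > n0)
    inv <- records[ii, ]
    k <- ceiling(n_inv / 2)
    inv$value[seq_len(k)] <- NaN
    if (n_inv > k) {
      inv$start_time[(k + 1):n_inv] <- as.POSIXct("1969-06-01 12:00:00", tz = "UTC")
      inv$end_time[(k + 1):n_inv] <- as.POSIXct("1969-06-01 12:30:00", tz = "UTC")
    }
    inv$injected <- "invalid"
    records <- bind_rows(records, inv)
  }

  r_dup <- config$duplicate_rate
  n_dup <- round(nrow(records) * r_dup / (1 - r_dup))
  if (n_dup > 0) {
    src <- which(records$injected != "invalid")
    ii <- sample(src, n_dup, replace = n_dup > length(src))
    dups <- records[ii, ]
    dups$injected <- "duplicate"
    records <- bind_rows(records, dups)
  }
  records |> arrange(.data$participant_id, .data$start_time, .data$variable)
}
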