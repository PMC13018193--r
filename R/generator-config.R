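#' Default per-group, per-variable, per-device distribution parameters
#'
#' Calibration table for the synthetic cohort generator. Count-like and
#' duration-like variables are modelled lognormal, parameterised by their
#' median (`p1`) and log-scale sd (`p2`, fitted as `log(Q3/Q1)/1.349` from
#' published interquartile ranges, or from a printed mean +/- SD via the
#' lognormal moment map). Heart-rate-like variables are Gaussian (`p1` mean,
#' `p2` sd) truncated to physiological bounds `[lo, hi]`.
#' `heartRateVariabilitySDNN` is kept lognormal because SDNN is strictly
#' positive and strongly right-skewed; a truncated Gaussian would displace its
#' median.
#'
#' The two `*PaceMax` rows are not emitted as records themselves: they set the
#' day-level maximum interval pace from which within-day activity intervals
#' are constructed, so the daily `StepCountPaceMax` recovered by the pace
#' pipeline follows the configured lognormal exactly.
#'
#' `class` drives modulation: `activity` rows receive weekend/seasonal
#' modulation and the post-diagnosis activity multiplier; `heart` rows receive
#' the post-diagnosis heart-rate multiplier; `sleep` and `fitness` rows are
#' unmodulated.
#'
#' @return A tibble with columns `device`, `variable`, `group`, `dist`,
#'   `p1`, `p2`, `lo`, `hi`, `class`.
#' @export
default_group_params <- function() {
  t <- tibble::tribble(
    ~device, ~variable,                  ~group,    ~dist,   ~p1,     ~p2,    ~lo,  ~hi,  ~class,
    # -- phone accelerometer stream -------------------------------------
    "phone", "stepCount",                "DC",      "lnorm", 3323,    0.888,  0,    9.9e4,  "activity",
    "phone", "stepCount",                "Healthy", "lnorm", 4620,    0.896,  0,    9.9e4,  "activity",
    "phone", "stepCount",                "IPAH",    "lnorm", 2596,    1.258,  0,    9.9e4,  "activity",
    "phone", "flightsClimbed",           "DC",      "lnorm", 3.20,    0.999,  0,    450,  "activity",
    "phone", "flightsClimbed",           "Healthy", "lnorm", 5.09,    1.184,  0,    450,  "activity",
    "phone", "flightsClimbed",           "IPAH",    "lnorm", 2.86,    1.242,  0,    450,  "activity",
    "phone", "StepCountPaceMax",         "DC",      "lnorm", 81.94,   0.470,  0,    Inf,  "activity",
    "phone", "StepCountPaceMax",         "Healthy", "lnorm", 101.2,   0.332,  0,    Inf,  "activity",
    "phone", "StepCountPaceMax",         "IPAH",    "lnorm", 86.92,   0.455,  0,    Inf,  "activity",
    "phone", "FlightsClimbedPaceMax",    "DC",      "lnorm", 1.20,    0.834,  0,    Inf,  "activity",
    "phone", "FlightsClimbedPaceMax",    "Healthy", "lnorm", 1.35,    1.022,  0,    Inf,  "activity",
    "phone", "FlightsClimbedPaceMax",    "IPAH",    "lnorm", 0.83,    1.275,  0,    Inf,  "activity",
    # -- watch accelerometer stream -------------------------------------
    "watch", "stepCount",                "DC",      "lnorm", 4693,    0.630,  0,    9.9e4,  "activity",
    "watch", "stepCount",                "Healthy", "lnorm", 7185,    0.679,  0,    9.9e4,  "activity",
    "watch", "stepCount",                "IPAH",    "lnorm", 4861,    0.818,  0,    9.9e4,  "activity",
    "watch", "flightsClimbed",           "DC",      "lnorm", 8.30,    1.279,  0,    450,  "activity",
    "watch", "flightsClimbed",           "Healthy", "lnorm", 10.22,   0.978,  0,    450,  "activity",
    "watch", "flightsClimbed",           "IPAH",    "lnorm", 4.33,    1.316,  0,    450,  "activity",
    "watch", "StepCountPaceMax",         "DC",      "lnorm", 97.89,   0.313,  0,    Inf,  "activity",
    "watch", "StepCountPaceMax",         "Healthy", "lnorm", 118.18,  0.186,  0,    Inf,  "activity",
    "watch", "StepCountPaceMax",         "IPAH",    "lnorm", 102.86,  0.255,  0,    Inf,  "activity",
    "watch", "FlightsClimbedPaceMax",    "DC",      "lnorm", 2.35,    1.308,  0,    Inf,  "activity",
    "watch", "FlightsClimbedPaceMax",    "Healthy", "lnorm", 3.08,    0.902,  0,    Inf,  "activity",
    "watch", "FlightsClimbedPaceMax",    "IPAH",    "lnorm", 1.36,    1.349,  0,    Inf,  "activity",
    "watch", "distanceWalkingRunning",   "DC",      "lnorm", 2800,    0.70,   0,    9.9e4,  "activity",
    "watch", "distanceWalkingRunning",   "Healthy", "lnorm", 4200,    0.70,   0,    9.9e4,  "activity",
    "watch", "distanceWalkingRunning",   "IPAH",    "lnorm", 2200,    0.80,   0,    9.9e4,  "activity",
    "watch", "activeEnergyBurned",       "DC",      "lnorm", 436.8,   0.463,  0,    9500,  "activity",
    "watch", "activeEnergyBurned",       "Healthy", "lnorm", 501.95,  0.581,  0,    9500,  "activity",
    "watch", "activeEnergyBurned",       "IPAH",    "lnorm", 353.7,   0.548,  0,    9500,  "activity",
    "watch", "appleStandTime",           "DC",      "lnorm", 1.63,    0.521,  0,    20,   "activity",
    "watch", "appleStandTime",           "Healthy", "lnorm", 1.82,    0.632,  0,    20,   "activity",
    "watch", "appleStandTime",           "IPAH",    "lnorm", 1.20,    0.795,  0,    20,   "activity",
    # -- watch PPG heart-rate stream ------------------------------------
    "watch", "restingHeartRate",         "DC",      "norm",  66.0,    11.12,  20,   250,  "heart",
    "watch", "restingHeartRate",         "Healthy", "norm",  62.0,    8.15,   20,   250,  "heart",
    "watch", "restingHeartRate",         "IPAH",    "norm",  64.0,    11.12,  20,   250,  "heart",
    "watch", "averageHeartRate",         "DC",      "norm",  79.64,   13.50,  20,   250,  "heart",
    "watch", "averageHeartRate",         "Healthy", "norm",  83.53,   19.69,  20,   250,  "heart",
    "watch", "averageHeartRate",         "IPAH",    "norm",  78.53,   13.05,  20,   250,  "heart",
    "watch", "walkingHeartRate",         "DC",      "norm",  97.0,    17.42,  30,   250,  "heart",
    "watch", "walkingHeartRate",         "Healthy", "norm",  96.5,    15.20,  30,   250,  "heart",
    "watch", "walkingHeartRate",         "IPAH",    "norm",  99.0,    16.31,  30,   250,  "heart",
    "watch", "heartRateVariabilitySDNN", "DC",      "lnorm", 24.72,   0.429,  0,    495,  "fitness",
    "watch", "heartRateVariabilitySDNN", "Healthy", "lnorm", 37.95,   0.367,  0,    495,  "fitness",
    "watch", "heartRateVariabilitySDNN", "IPAH",    "lnorm", 29.93,   0.538,  0,    495,  "fitness",
    "watch", "VO2Max",                   "DC",      "norm",  23.8,    9.9,    10,   80,   "fitness",
    "watch", "VO2Max",                   "Healthy", "norm",  37.4,    6.34,   10,   80,   "fitness",
    "watch", "VO2Max",                   "IPAH",    "norm",  26.26,   7.15,   10,   80,   "fitness",
    "watch", "basalEnergyBurned",        "DC",      "lnorm", 1829.83, 0.213,  0,    5900,  "fitness",
    "watch", "basalEnergyBurned",        "Healthy", "lnorm", 1642.18, 0.157,  0,    5900,  "fitness",
    "watch", "basalEnergyBurned",        "IPAH",    "lnorm", 1680.32, 0.174,  0,    5900,  "fitness",
    # -- watch sleep stream ---------------------------------------------
    "watch", "Asleep",                   "DC",      "lnorm", 7.37,    0.195,  0,    16,   "sleep",
    "watch", "Asleep",                   "Healthy", "lnorm", 6.35,    0.493,  0,    16,   "sleep",
    "watch", "Asleep",                   "IPAH",    "lnorm", 6.63,    0.337,  0,    16,   "sleep",
    "watch", "Awake",                    "DC",      "lnorm", 0.59,    0.647,  0,    12,   "sleep",
    "watch", "Awake",                    "Healthy", "lnorm", 0.15,    0.955,  0,    12,   "sleep",
    "watch", "Awake",                    "IPAH",    "lnorm", 0.41,    1.328,  0,    12,   "sleep"
  )
  t
}

#' Default 24-hour circadian weight profile
#'
#' Relative propensity of activity being recorded in each hour of the day
#' (index 1 = 00:00-01:00). Used to place within-day activity intervals and
#' to share the daily total across them; it does not change daily totals.
#'
#' @return Numeric vector of length 24.
#' @export
default_circadian_profile <- function() {
  c(0.20, 0.10, 0.05, 0.05, 0.05, 0.10, 0.50, 1.00, 1.20, 1.10, 1.00, 1.10,
    1.20, 1.10, 1.00, 1.00, 1.10, 1.30, 1.20, 1.00, 0.80, 0.60, 0.40, 0.30)
}

#' Default US-vs-UK region drift multipliers
#'
#' Multiplicative shifts applied to the US cohort's distribution parameters.
#' Pace variables use the ratio of the published pooled maximum-step-pace
#' medians (86/112); activity volumes are reduced by a nominal 25% reflecting
#' the reported lower physical-activity levels in the external cohort; heart
#' and sleep variables are left undrifted.
#'
#' @return Named numeric vector of per-variable multipliers.
#' @export
default_region_drift <- function() {
  c(stepCount = 0.75,
    flightsClimbed = 0.75,
    distanceWalkingRunning = 0.75,
    StepCountPaceMax = 86 / 112,
    FlightsClimbedPaceMax = 86 / 112)
}

#' Build a synthetic-cohort generator configuration
#'
#' Central configuration object for [generate_cohort()]. Defaults encode the
#' study conditions the generator emulates: cohort sizes proportional to the
#' published roster, group/variable/device distributions calibrated to the
#' published medians and IQRs, diurnal/weekly/seasonal modulation, a
#' post-diagnosis recovery effect for IPAH participants, and contamination
#' (exact duplicates, daily-plausibility outliers, invalid rows, short and
#' month-long gaps) at the published cleaning rates.
#'
#' @param n_per_group Named integer vector of participants per group
#'   (`IPAH`, `DC`, `Healthy`).
#' @param date_span Days of observation per participant.
#' @param group_params Distribution calibration table, see
#'   [default_group_params()].
#' @param pace_calibration Scalar multiplier applied to the `*PaceMax` medians
#'   so the pooled (all-group, both-device) median of daily maximum step pace
#'   matches the published pooled value; see the methods vignette.
#' @param circadian_profile 24 positive weights, see
#'   [default_circadian_profile()].
#' @param weekend_effect Named per-group weekend/weekday activity ratio
#'   (values < 1 mean quieter weekends). Applied as a median-preserving
#'   weekly contrast.
#' @param seasonal_amplitude Amplitude of the annual log-scale sinusoidal
#'   modulation of activity (0 disables).
#' @param prepost_effect Named list with `activity` and `heart` multipliers
#'   applied to IPAH records on/after the diagnosis date (treatment response:
#'   activity recovers, heart rates fall).
#' @param missingness Named list with `short_gap` (per participant-day drop
#'   probability) and `long_gap` (per calendar-month whole-month drop
#'   probability).
#' @param duplicate_rate Fraction of the emitted record stream that is an
#'   exact duplicate of another record.
#' @param outlier_rate Fraction of unique records whose value is pushed
#'   outside the daily-plausibility bounds.
#' @param outlier_magnitude Multiplier (> 1) of the variable's upper bound
#'   used when planting outliers.
#' @param invalid_rate Fraction of rows given a non-finite value or an
#'   illogical date.
#' @param device_split Probability that a participant contributes watch
#'   records (every participant contributes phone records).
#' @param region_drift Named per-variable multipliers for the US region, see
#'   [default_region_drift()].
#' @param quest_shift Named per-group latent shifts for non-calibrated
#'   questionnaire items (negative = less favourable responses).
#' @param start_date First possible consent date (cohort recruiting window).
#' @param variables Optional character vector restricting generation to a
#'   subset of variables (pace meta-variables included automatically when
#'   their base count variable is kept).
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   output.
#' @return An object of class `pw_config` (a validated list).
#' @export
generator_config <- function(n_per_group = c(IPAH = 30L, DC = 15L, Healthy = 60L),
                             date_span = 365L,
                             group_params = default_group_params(),
                             pace_calibration = 1.029,
                             circadian_profile = default_circadian_profile(),
                             weekend_effect = c(IPAH = 1.0, DC = 0.9, Healthy = 0.85),
                             seasonal_amplitude = 0.08,
                             prepost_effect = list(activity = 1.3, heart = 0.95),
                             missingness = list(short_gap = 0.08, long_gap = 0.03),
                             duplicate_rate = 0.15,
                             outlier_rate = 0.137,
                             outlier_magnitude = 3,
                             invalid_rate = 1e-4,
                             device_split = 1.0,
                             region_drift = default_region_drift(),
                             quest_shift = c(IPAH = -0.8, DC = -0.3, Healthy = 0),
                             start_date = as.Date("2021-01-01"),
                             variables = NULL,
                             seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, date_span = as.integer(date_span),
    group_params = group_params, pace_calibration = pace_calibration,
    circadian_profile = circadian_profile, weekend_effect = weekend_effect,
    seasonal_amplitude = seasonal_amplitude, prepost_effect = prepost_effect,
    missingness = missingness, duplicate_rate = duplicate_rate,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    invalid_rate = invalid_rate, device_split = device_split,
    region_drift = region_drift, quest_shift = quest_shift,
    start_date = as.Date(start_date), variables = variables,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pw_config")
}

validate_config <- function(cfg) {
  if (!all(c("IPAH", "DC", "Healthy") %in% names(cfg$n_per_group))) {
    rlang::abort("`n_per_group` must name IPAH, DC and Healthy.",
                 class = "phenowear_config_error")
  }
  if (cfg$date_span < 1L) {
    rlang::abort("`date_span` must be >= 1 day.", class = "phenowear_config_error")
  }
  assert_prob(cfg$duplicate_rate, "duplicate_rate")
  assert_prob(cfg$outlier_rate, "outlier_rate")
  assert_prob(cfg$invalid_rate, "invalid_rate")
  assert_prob(cfg$device_split, "device_split")
  assert_prob(cfg$missingness$short_gap, "missingness$short_gap")
  assert_prob(cfg$missingness$long_gap, "missingness$long_gap")
  assert_positive(cfg$circadian_profile, "circadian_profile")
  assert_positive(cfg$pace_calibration, "pace_calibration")
  gp <- cfg$group_params
  req <- c("device", "variable", "group", "dist", "p1", "p2", "lo", "hi", "class")
  if (!all(req %in% names(gp))) {
    rlang::abort("`group_params` is missing required columns.",
                 class = "phenowear_config_error")
  }
  if (any(!is.finite(gp$p1)) || any(gp$p1 <= 0 & gp$dist == "lnorm") ||
      any(!is.finite(gp$p2)) || any(gp$p2 <= 0)) {
    rlang::abort("`group_params` locations/scales must be positive.",
                 class = "phenowear_config_error")
  }
  invisible(cfg)
}

#' @export
print.pw_config <- function(x, ...) {
  cat("<phenowear generator config>\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                          collapse = ", "), "\n", sep = "")
  cat("  span:   ", x$date_span, " days from ", format(x$start_date), "\n", sep = "")
  cat("  contamination: dup=", x$duplicate_rate, " outlier=", x$outlier_rate,
      " invalid=", x$invalid_rate, "\n", sep = "")
  cat("  seed:   ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' Scalar and vector fields round-trip through YAML; the `group_params`
#' calibration table is stored as a list of rows.
#'
#' @param path File path.
#' @param config A `pw_config` object.
#' @return `read_generator_config()` returns a `pw_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "pw_config"))
  out <- unclass(config)
  out$start_date <- format(out$start_date)
  out$group_params <- purrr::transpose(as.list(config$group_params))
  # named atomic vectors must become maps, not bare sequences
  for (nm in c("n_per_group", "weekend_effect", "region_drift", "quest_shift")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$group_params <- dplyr::bind_rows(lapply(raw$group_params, tibble::as_tibble))
  raw$group_params$hi <- as.numeric(raw$group_params$hi)
  raw$n_per_group <- unlist(raw$n_per_group)
  raw$weekend_effect <- unlist(raw$weekend_effect)
  raw$region_drift <- unlist(raw$region_drift)
  raw$quest_shift <- unlist(raw$quest_shift)
  raw$circadian_profile <- unlist(raw$circadian_profile)
  do.call(generator_config, raw)
}
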