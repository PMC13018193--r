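#' Catalogue of supported HealthKit-style variables
#'
#' One row per variable with its unit, measurement kind and the daily
#' aggregation rule: `count` variables (steps, flights, energy, distance,
#' stand time) are summed over a day, `rate` variables (heart rates, HRV,
#' VO2Max) are averaged, and `duration` variables (sleep states) are summed.
#'
#' @return A tibble with columns `variable`, `unit`, `kind`, `daily_agg`.
#' @export
variable_catalog <- function() {
  tibble::tribble(
    ~variable,                  ~unit,            ~kind,      ~daily_agg,
    "stepCount",                "steps",          "count",    "sum",
    "flightsClimbed",           "flights",        "count",    "sum",
    "distanceWalkingRunning",   "m",              "count",    "sum",
    "activeEnergyBurned",       "kcal",           "count",    "sum",
    "basalEnergyBurned",        "kcal",           "count",    "sum",
    "appleStandTime",           "hr",             "count",    "sum",
    "restingHeartRate",         "beats/min",      "rate",     "mean",
    "averageHeartRate",         "beats/min",      "rate",     "mean",
    "walkingHeartRate",         "beats/min",      "rate",     "mean",
    "heartRateVariabilitySDNN", "ms",             "rate",     "mean",
    "VO2Max",                   "mL O2/kg/min",   "rate",     "mean",
    "Asleep",                   "hr",             "duration", "sum",
    "Awake",                    "hr",             "duration", "sum",
    "TimeInBed",                "hr",             "duration", "sum",
    "inBed",                    "hr",             "duration", "sum"
  )
}

#' Default daily-plausibility bounds
#'
#' Per-variable lower/upper bounds on what a single record (equivalently, the
#' most extreme value achievable within one day) can plausibly hold. Values
#' outside the bounds are treated as sensor or pipeline artefacts and removed
#' by [filter_outliers()]. The defaults are deliberately generous physiological
#' envelopes and are fully configurable.
#'
#' @return A tibble with columns `variable`, `lower`, `upper`.
#' @export
default_bounds <- function() {
  tibble::tribble(
    ~variable,                  ~lower, ~upper,
    "stepCount",                0,      1e5,
    "flightsClimbed",           0,      500,
    "distanceWalkingRunning",   0,      1e5,
    "activeEnergyBurned",       0,      1e4,
    "basalEnergyBurned",        200,    6e3,
    "appleStandTime",           0,      24,
    "restingHeartRate",         20,     250,
    "averageHeartRate",         20,     250,
    "walkingHeartRate",         20,     250,
    "heartRateVariabilitySDNN", 0,      500,
    "VO2Max",                   5,      95,
    "Asleep",                   0,      24,
    "Awake",                    0,      24,
    "TimeInBed",                0,      24,
    "inBed",                    0,      24
  )
}
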