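# Calculated activity, heart-rate and sleep metrics derived from cleaned
# records and daily aggregates: interval paces and their daily summaries,
# heart-rate reserve, cardiac effort, the bed-bound flag, and the
# duration-weighted fraction of active time above 70% of maximum pace.

#' Pace of a single measured interval
#'
#' Pace is the activity count divided by the interval duration, expressed per
#' minute. Intervals shorter than 0.5 s are excluded (too short for a
#' meaningful rate).
#'
#' @param count Steps or flights in the interval (>= 0).
#' @param start,end Interval timestamps (POSIXct or numeric seconds).
#' @param activity `"steps"` or `"flights"`.
#' @return A one-row tibble (`t_i` seconds, `P_i` units/min, `activity`), or
#'   `NULL` when the interval is excluded.
#' @export
interval_pace <- function(count, start, end, activity = c("steps", "flights")) {
  activity <- match.arg(activity)
  dur <- as.numeric(end) - as.numeric(start)
  if (is.na(dur) || dur < 0) {
    rlang::abort("Negative interval duration.", class = "phenowear_record_error")
  }
  if (count < 0) {
    rlang::abort("Negative activity count.", class = "phenowear_record_error")
  }
  if (dur < 0.5) return(NULL)
  tibble::tibble(t_i = dur, P_i = count / dur * 60, activity = activity)
}

# vectorised internal version used by the pipeline
interval_pace_vec <- function(count, start, end) {
  dur <- as.numeric(end) - as.numeric(start)
  keep <- !is.na(dur) & dur >= 0.5 & !is.na(count)
  list(keep = keep, t_i = dur, P_i = ifelse(dur > 0, count / dur * 60, 0))
}

#' Daily pace summary
#'
#' Mean and maximum interval pace for one day's (non-excluded) intervals of
#' one activity. With no intervals the summary is absent (never zero).
#'
#' @param paces Numeric vector of interval paces (units/min).
#' @return A one-row tibble with `PaceMean` and `PaceMax`, or `NULL`.
#' @export
day_pace_summary <- function(paces) {
  paces <- paces[!is.na(paces)]
  if (length(paces) == 0) return(NULL)
  tibble::tibble(PaceMean = mean(paces), PaceMax = max(paces))
}

#' Heart-rate reserve
#'
#' Daily average heart rate minus resting heart rate (beats/min). A negative
#' reserve (resting above the daily average) is retained but flagged.
#'
#' @param averageHeartRate,restingHeartRate Daily values (beats/min).
#' @return Named list with `value` and `flag_negative`; `value` is `NA` if
#'   either input is missing.
#' @export
heart_rate_reserve <- function(averageHeartRate, restingHeartRate) {
  value <- averageHeartRate - restingHeartRate
  list(value = value, flag_negative = !is.na(value) & value < 0)
}

#' Cardiac effort
#'
#' Walking heart rate divided by walking speed; speed is distance over
#' duration, in m/s by default. Undefined (absent) when distance or duration
#' is not positive.
#'
#' @param walkingHeartRate Daily walking heart rate (beats/min).
#' @param distance Distance walked (m).
#' @param duration Walking duration (seconds).
#' @param speed_unit `"m/s"` (default) or `"km/h"`.
#' @return Numeric value (beats/min per unit speed) or `NA`.
#' @export
cardiac_effort <- function(walkingHeartRate, distance, duration,
                           speed_unit = c("m/s", "km/h")) {
  speed_unit <- match.arg(speed_unit)
  bad <- is.na(distance) | is.na(duration) | is.na(walkingHeartRate) |
    distance <= 0 | duration <= 0
  speed <- distance / duration                     # m/s
  if (speed_unit == "km/h") speed <- speed * 3.6
  out <- walkingHeartRate / speed
  out[bad] <- NA_real_
  out
}

#' Bed-bound flag
#'
#' TRUE when time in bed reaches at least 18 hours in a day.
#'
#' @param inBed Hours in bed for the day, in `[0, 24]`.
#' @return Logical vector.
#' @export
bed_bound <- function(inBed) {
  if (any(!is.na(inBed) & (inBed < 0 | inBed > 24))) {
    rlang::abort("`inBed` must lie in [0, 24] hours.", class = "phenowear_validation_error")
  }
  !is.na(inBed) & inBed >= 18
}

#' Fraction of active time above 70% of maximum pace
#'
#' Duration-weighted proportion of a day's positive-pace time spent above
#' 70% of the reference maximum pace `P_max`:
#' sum of t_i over intervals with P_i > 0.7 P_max, divided by the sum of t_i
#' over intervals with P_i > 0. By default `P_max` is the participant's
#' overall maximum pace across all intervals of the observation period
#' (configurable to the day's own maximum via the pipeline).
#'
#' @param t_i Interval durations (seconds).
#' @param P_i Interval paces (units/min).
#' @param P_max Reference maximum pace (> 0).
#' @return Fraction in `[0, 1]`, or `NA` when no positive-pace time exists.
#' @export
pace_higher_70pct <- function(t_i, P_i, P_max) {
  stopifnot(length(t_i) == length(P_i))
  if (is.na(P_max) || P_max <= 0) {
    rlang::abort("`P_max` must be positive.", class = "phenowear_validation_error")
  }
  pos <- !is.na(P_i) & P_i > 0
  denom <- sum(t_i[pos])
  if (denom == 0) return(NA_real_)
  sum(t_i[pos & P_i > 0.7 * P_max]) / denom
}

#' Add derived metrics to the daily table
#'
#' Computes, per participant-day-device: mean/max step and climb paces from
#' the interval records, the above-70%-of-max fractions (participant-level
#' `P_max` by default), heart-rate reserve, cardiac effort (using the day's
#' total walking-interval duration), and the bed-bound flag; and joins them
#' onto the wide daily aggregate table.
#'
#' @param records Cleaned record tibble (interval-level).
#' @param daily Long daily table from [aggregate_records()].
#' @param pmax_scope `"participant"` (default) or `"day"`: reference set for
#'   the maximum pace in the above-70% fraction.
#' @return Wide daily tibble with derived-metric columns
#'   (`StepCountPaceMean`, `StepCountPaceMax`, `FlightsClimbedPaceMean`,
#'   `FlightsClimbedPaceMax`, `StepPaceHigher70pct`, `FlightsPaceHigher70pct`,
#'   `HeartRateReserve`, `HeartRateReserveNegative`, `CardiacEffort`,
#'   `BedBound`).
#' @export
derive_daily_metrics <- function(records, daily,
                                 pmax_scope = c("participant", "day")) {
  pmax_scope <- match.arg(pmax_scope)
  wide <- daily_wide(daily)

  pace_tbl <- function(var, prefix) {
    r <- records[records$variable == var, ]
    if (nrow(r) == 0) return(NULL)
    ip <- interval_pace_vec(r$value, r$start_time, r$end_time)
    r <- r[ip$keep, ]
    t_i <- ip$t_i[ip$keep]
    P_i <- ip$P_i[ip$keep]
    r$date <- lubridate::as_date(r$start_time)
    g <- paste(r$participant_id, r$date, r$device, sep = "\r")
    u <- r[!duplicated(g), c("participant_id", "date", "device")]
    gk <- g[!duplicated(g)]
    pmax_day <- tapply(P_i, g, max)[gk]
    pmean_day <- (rowsum(P_i, g) / rowsum(rep(1, length(P_i)), g))[, 1][gk]
    dur_day <- rowsum(t_i, g)[, 1][gk]
    ref <- if (pmax_scope == "participant") {
      pp <- tapply(P_i, paste(r$participant_id, r$device, sep = "\r"), max)
      unname(pp[paste(u$participant_id, u$device, sep = "\r")])
    } else unname(pmax_day)
    ref_row <- ref[match(g, gk)]
    hi <- rowsum(t_i * (P_i > 0.7 * ref_row), g)[, 1][gk]
    pos <- rowsum(t_i * (P_i > 0), g)[, 1][gk]
    u[[paste0(prefix, "PaceMean")]] <- unname(pmean_day)
    u[[paste0(prefix, "PaceMax")]] <- unname(as.numeric(pmax_day))
    u[[paste0(sub("Count$|Climbed$", "", prefix), "PaceHigher70pct")]] <-
      ifelse(pos > 0, hi / pos, NA_real_)
    u[[paste0(prefix, "Duration")]] <- unname(dur_day)
    tibble::as_tibble(u)
  }

  steps <- pace_tbl("stepCount", "StepCount")
  flights <- pace_tbl("flightsClimbed", "FlightsClimbed")
  by <- c("participant_id", "date", "device")
  if (!is.null(steps)) wide <- left_join(wide, steps, by = by)
  if (!is.null(flights)) wide <- left_join(wide, flights, by = by)

  if (all(c("averageHeartRate", "restingHeartRate") %in% names(wide))) {
    hrr <- heart_rate_reserve(wide$averageHeartRate, wide$restingHeartRate)
    wide$HeartRateReserve <- hrr$value
    wide$HeartRateReserveNegative <- hrr$flag_negative
  }
  if (all(c("walkingHeartRate", "distanceWalkingRunning") %in% names(wide)) &&
      "StepCountDuration" %in% names(wide)) {
    wide$CardiacEffort <- cardiac_effort(wide$walkingHeartRate,
                                         wide$distanceWalkingRunning,
                                         wide$StepCountDuration)
  }
  if ("inBed" %in% names(wide)) {
    wide$BedBound <- bed_bound(pmin(wide$inBed, 24))
  }
  wide$StepCountDuration <- NULL
  wide$FlightsClimbedDuration <- NULL
  wide
}
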