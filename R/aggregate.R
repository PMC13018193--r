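#' Aggregate cleaned records to daily or hourly level
#'
#' Counts (steps, flights, energy, distance, stand time) are summed within a
#' period, rate-like variables (heart rates, HRV, VO2Max) are averaged, and
#' sleep durations are summed, separately per participant, period and device.
#' Devices are never merged. A record belongs to the period of its
#' `start_time` (local-midnight, half-open day). Periods with no records are
#' absent, not zero-filled.
#'
#' @param records Cleaned record tibble.
#' @param level `"daily"` or `"hourly"`.
#' @return A long tibble with `participant_id`, `date` (and `hour` for
#'   hourly), `device`, `variable`, `value`.
#' @export
aggregate_records <- function(records, level = c("daily", "hourly")) {
  level <- match.arg(level)
  cat_ <- variable_catalog()
  agg <- setNames(cat_$daily_agg, cat_$variable)
  unknown <- setdiff(unique(records$variable), cat_$variable)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")),
                 class = "phenowear_config_error")
  }
  r <- records |>
    mutate(date = lubridate::as_date(.data$start_time),
           .agg = unname(agg[.data$variable]))
  keys <- c("participant_id", "date", "device", "variable")
  if (level == "hourly") {
    r <- r |> mutate(hour = lubridate::hour(.data$start_time))
    keys <- c(keys, "hour")
  }
  # rowsum-based aggregation: orders of magnitude faster than per-group
  # closures at millions of records
  key <- do.call(paste, c(r[keys], list(sep = "\r")))
  u <- r[!duplicated(key), c(keys, ".agg")]
  u_key <- key[!duplicated(key)]
  sums <- rowsum(r$value, key)
  cnts <- rowsum(rep(1, nrow(r)), key)
  m <- match(u_key, rownames(sums))
  u$value <- ifelse(u$.agg == "mean", sums[m] / cnts[m], sums[m])
  u |>
    select(-".agg") |>
    arrange(.data$participant_id, .data$date, .data$device, .data$variable) |>
    tibble::as_tibble()
}

#' Pivot a long daily table to one row per participant-day-device
#'
#' @param daily Long daily tibble from [aggregate_records()].
#' @return Wide tibble, one column per variable.
#' @export
daily_wide <- function(daily) {
  id_cols <- intersect(c("participant_id", "date", "device", "phase", "group"),
                       names(daily))
  tidyr::pivot_wider(daily, id_cols = dplyr::all_of(id_cols),
                     names_from = "variable", values_from = "value")
}

#' Tag daily rows with the diagnosis phase
#'
#' Rows dated strictly before an IPAH participant's diagnosis date are `pre`,
#' on/after are `post` (same-day rows count as post since treatment can start
#' the day of diagnosis); rows from non-IPAH participants are `control`.
#'
#' @param daily Daily tibble with `participant_id` and `date`.
#' @param participants Roster with `id`, `group`, `diagnosis_date`.
#' @return `daily` with a `phase` column.
#' @export
tag_diagnosis_phase <- function(daily, participants) {
  ipah_missing <- participants$group == "IPAH" & is.na(participants$diagnosis_date)
  if (any(ipah_missing)) {
    rlang::abort(paste0("IPAH participant(s) without diagnosis date: ",
                        paste(participants$id[ipah_missing], collapse = ", ")),
                 class = "phenowear_roster_error")
  }
  daily |>
    left_join(participants[, c("id", "group", "diagnosis_date")],
              by = c(participant_id = "id")) |>
    mutate(phase = dplyr::case_when(
      .data$group != "IPAH" ~ "control",
      .data$date < .data$diagnosis_date ~ "pre",
      TRUE ~ "post"
    )) |>
    select(-"diagnosis_date")
}
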