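#' Remove exact duplicate records
#'
#' Records that agree on every schema field (participant, variable, value,
#' unit, timestamps, device, region) are collapsed to a single copy. Such
#' duplicates typically arise from software updates or queued uploads in the
#' collection pipeline.
#'
#' @param records Record tibble.
#' @return A list with `records` (deduplicated) and `n_removed`.
#' @export
deduplicate <- function(records) {
  cols <- intersect(record_schema_cols(), names(records))
  dup <- duplicated(records[, cols])
  list(records = records[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Remove records outside daily-plausibility bounds
#'
#' A record whose value could not plausibly be achieved within a single day
#' (per-variable lower/upper bounds, [default_bounds()]) is treated as a
#' sensor or pipeline artefact and removed.
#'
#' @param records Record tibble.
#' @param bounds Bounds tibble (`variable`, `lower`, `upper`); every variable
#'   present in `records` must have bounds, otherwise a configuration error
#'   is raised.
#' @return A list with `records` and `n_removed`.
#' @export
filter_outliers <- function(records, bounds = default_bounds()) {
  if (any(bounds$lower >= bounds$upper)) {
    rlang::abort("Bounds must satisfy lower < upper.", class = "phenowear_config_error")
  }
  missing_vars <- setdiff(unique(records$variable), bounds$variable)
  if (length(missing_vars) > 0) {
    rlang::abort(paste0("No bounds defined for variable(s): ",
                        paste(missing_vars, collapse = ", ")),
                 class = "phenowear_config_error")
  }
  lo <- setNames(bounds$lower, bounds$variable)[records$variable]
  hi <- setNames(bounds$upper, bounds$variable)[records$variable]
  out <- !is.na(records$value) & is.finite(records$value) &
    (records$value < lo | records$value > hi)
  list(records = records[!out, , drop = FALSE], n_removed = sum(out))
}

#' Remove invalid records
#'
#' Drops rows with non-finite values, unparseable or illogical timestamps
#' (before 1970 or outside an optional study window), or end before start.
#' No imputation is performed; missing data stay missing.
#'
#' @param records Record tibble (a `.invalid` flag from [read_records()] is
#'   honoured if present).
#' @param study_window Optional length-2 Date vector; records starting
#'   outside it are treated as illogical.
#' @return A list with `records` and `n_removed`.
#' @export
drop_invalid <- function(records, study_window = NULL) {
  bad <- !is.finite(records$value)
  if (".invalid" %in% names(records)) bad <- bad | records$.invalid
  st <- records$start_time
  en <- records$end_time
  bad <- bad | is.na(st) | is.na(en)
  ok <- !is.na(st) & !is.na(en)
  bad[ok] <- bad[ok] | (en[ok] < st[ok]) |
    (st[ok] < as.POSIXct("1970-01-01", tz = "UTC"))
  if (!is.null(study_window)) {
    sw <- as.POSIXct(as.Date(study_window), tz = "UTC")
    bad[ok] <- bad[ok] | st[ok] < sw[1] | st[ok] > (sw[2] + 86399)
  }
  list(records = records[!bad, , drop = FALSE], n_removed = sum(bad))
}

#' Full cleaning chain
#'
#' Applies [drop_invalid()], [deduplicate()] and [filter_outliers()] in
#' order and reports per-stage removal counts. The chain is idempotent and
#' the dedup/outlier stages commute.
#'
#' @inheritParams filter_outliers
#' @inheritParams drop_invalid
#' @return A list with `records` and a named `removed` vector
#'   (`invalid`, `duplicate`, `outlier`).
#' @export
clean_records <- function(records, bounds = default_bounds(), study_window = NULL) {
  s1 <- drop_invalid(records, study_window)
  s2 <- deduplicate(s1$records)
  s3 <- filter_outliers(s2$records, bounds)
  list(records = s3$records,
       removed = c(invalid = s1$n_removed, duplicate = s2$n_removed,
                   outlier = s3$n_removed))
}
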