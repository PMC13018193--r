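#' Read raw records from CSV or JSONL
#'
#' Parses a long-format record file (columns `participant_id`, `variable`,
#' `value`, `unit`, `start_time`, `end_time`, `device`, `region`) into typed
#' records. Malformed rows are flagged in the logical `.invalid` column with a
#' reason, never silently dropped; [drop_invalid()] removes them.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"` (guessed from the extension by default).
#' @return A tibble of records with parsing flags.
#' @export
read_records <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "phenowear_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0) tibble::tibble() else
      dplyr::bind_rows(lapply(lines, function(l) {
        tibble::as_tibble(lapply(jsonlite::fromJSON(l), as.character))
      }))
  }
  if (nrow(raw) == 0) {
    rlang::warn("Empty record file; returning an empty collection.")
    return(empty_records())
  }
  need <- setdiff(record_schema_cols(), names(raw))
  if (length(need) > 0) {
    rlang::abort(paste0("Missing required column(s): ", paste(need, collapse = ", ")),
                 class = "phenowear_schema_error")
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    variable = raw$variable,
    value = suppressWarnings(as.numeric(raw$value)),
    unit = raw$unit,
    start_time = suppressWarnings(lubridate::ymd_hms(raw$start_time, tz = "UTC", quiet = TRUE)),
    end_time = suppressWarnings(lubridate::ymd_hms(raw$end_time, tz = "UTC", quiet = TRUE)),
    device = raw$device,
    region = raw$region
  )
  out$.invalid <- is.na(out$value) | is.na(out$start_time) | is.na(out$end_time) |
    (!is.na(out$start_time) & !is.na(out$end_time) & out$end_time < out$start_time)
  out$.invalid_reason <- dplyr::case_when(
    is.na(out$value) ~ "non-numeric value",
    is.na(out$start_time) | is.na(out$end_time) ~ "unparseable timestamp",
    out$end_time < out$start_time ~ "end before start",
    TRUE ~ NA_character_
  )
  n_bad <- sum(out$.invalid)
  if (n_bad > 0) {
    rlang::inform(sprintf("%d malformed row(s) flagged in `.invalid`.", n_bad))
  }
  out
}

empty_records <- function() {
  tibble::tibble(
    participant_id = character(), variable = character(), value = numeric(),
    unit = character(),
    start_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"),
    device = character(), region = character(),
    .invalid = logical(), .invalid_reason = character()
  )
}

#' Write records to CSV or JSONL
#'
#' @param records Record tibble (schema columns are written; internal columns
#'   such as the generator's `injected` label are not).
#' @param path Destination path; `.jsonl` extension selects JSON lines.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, intersect(record_schema_cols(), names(records))]
  out$start_time <- format(out$start_time, "%Y-%m-%d %H:%M:%S")
  out$end_time <- format(out$end_time, "%Y-%m-%d %H:%M:%S")
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1)), con)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
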