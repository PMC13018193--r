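# Participant-level featurization: monthly aggregation of daily values, the
# 26 time-/frequency-domain/autoregressive features per (variable, device)
# series, and questionnaire block encoding.

#' Aggregate daily metrics to calendar months
#'
#' Calendar-month mean of the available daily values per participant,
#' variable and device; months with no data are absent (no imputation).
#'
#' @param daily Long daily table (optionally phase-tagged; filter before
#'   calling for phase-restricted series).
#' @return Tibble `participant_id`, `device`, `variable`, `month`
#'   (first-of-month Date), `value`.
#' @export
monthly_aggregate <- function(daily) {
  daily |>
    filter(!is.na(.data$value)) |>
    mutate(month = lubridate::floor_date(.data$date, "month")) |>
    group_by(.data$participant_id, .data$device, .data$variable, .data$month) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    arrange(.data$participant_id, .data$device, .data$variable, .data$month)
}

feature_names <- function() {
  c("cc_lag0", "cc_lag1", "cc_lag2", "N", "MAX", "MIN", "P2P", "RMS", "STD",
    "VAR", "MEAN", "PEAK", "SKEW", "KURTOSIS", "CREST_FACTOR",
    "MAX_f", "MEAN_f", "VAR_f", "SUM_f", "PEAK_f", "SKEW_f", "KURTOSIS_f",
    "POWER", "ar.L1", "ar.L2", "sigma2")
}

# standardised central moments with population (1/N) denominators
moment_skew <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

autocorr <- function(x, lag) {
  n <- length(x)
  if (n < lag + 1) return(NA_real_)
  m <- mean(x)
  denom <- sum((x - m)^2)
  if (denom == 0) return(if (lag == 0) 1 else NA_real_)
  sum((x[seq_len(n - lag)] - m) * (x[seq_len(n - lag) + lag] - m)) / denom
}

#' Time-domain features of a monthly series
#'
#' Macro-statistical descriptors of the compacted (missing dropped) series:
#' count, extremes, peak-to-peak, mean, sample variance/SD (N-1), RMS, peak
#' absolute value, crest factor (PEAK/RMS), skewness and excess kurtosis
#' (standardised central moments), and sample autocorrelation at lags 0-2.
#' Features whose minimum length requirement is not met are `NA`, never
#' fabricated.
#'
#' @param x Numeric series (missing values dropped).
#' @return Named numeric vector.
#' @export
time_domain_features <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  out <- setNames(rep(NA_real_, 15),
                  c("cc_lag0", "cc_lag1", "cc_lag2", "N", "MAX", "MIN", "P2P",
                    "RMS", "STD", "VAR", "MEAN", "PEAK", "SKEW", "KURTOSIS",
                    "CREST_FACTOR"))
  out["N"] <- n
  if (n == 0) return(out)
  out["MAX"] <- max(x)
  out["MIN"] <- min(x)
  out["P2P"] <- max(x) - min(x)
  out["MEAN"] <- mean(x)
  rms <- sqrt(mean(x^2))
  out["RMS"] <- rms
  out["PEAK"] <- max(abs(x))
  out["CREST_FACTOR"] <- if (rms > 0) max(abs(x)) / rms else NA_real_
  if (n >= 2) {
    out["VAR"] <- stats::var(x)
    out["STD"] <- stats::sd(x)
  }
  if (n >= 3) out["SKEW"] <- moment_skew(x)
  if (n >= 4) out["KURTOSIS"] <- moment_kurtosis(x)
  out["cc_lag0"] <- if (n >= 1) autocorr(x, 0) else NA_real_
  if (n >= 2) out["cc_lag1"] <- autocorr(x, 1)
  if (n >= 3) out["cc_lag2"] <- autocorr(x, 2)
  out
}

#' Frequency-domain features of a monthly series
#'
#' Discrete-Fourier magnitude spectrum of the mean-centred series, DC bin
#' excluded. `MAX_f`, `MEAN_f`, `VAR_f`, `SUM_f`, `PEAK_f`, `SKEW_f`,
#' `KURTOSIS_f` are the time-domain statistics applied to the magnitude
#' spectrum, and `POWER = sum(|F_k|^2) / (N (N - 1))` which by Parseval's
#' identity equals the sample variance of the series. Requires at least 4
#' contiguous observations.
#'
#' @param x Numeric series (the longest contiguous non-missing run is used).
#' @return Named numeric vector of the 8 spectral features.
#' @export
freq_domain_features <- function(x) {
  out <- setNames(rep(NA_real_, 8),
                  c("MAX_f", "MEAN_f", "VAR_f", "SUM_f", "PEAK_f", "SKEW_f",
                    "KURTOSIS_f", "POWER"))
  x <- longest_run(x)
  n <- length(x)
  if (n < 4) return(out)
  z <- x - mean(x)
  m <- Mod(stats::fft(z))[-1]
  out["MAX_f"] <- max(m)
  out["MEAN_f"] <- mean(m)
  out["VAR_f"] <- stats::var(m)
  out["SUM_f"] <- sum(m)
  out["PEAK_f"] <- max(abs(m))
  out["SKEW_f"] <- moment_skew(m)
  out["KURTOSIS_f"] <- moment_kurtosis(m)
  out["POWER"] <- sum(m^2) / (n * (n - 1))
  out
}

#' Autoregressive features of a monthly series
#'
#' AR(2)-with-intercept coefficients and innovation variance fitted by
#' maximum likelihood ([stats::arima()]). Requires at least 8 contiguous
#' months (the longest contiguous run is used); non-convergent or degenerate
#' fits yield missing features with a warning.
#'
#' @param x Numeric series.
#' @param min_n Minimum contiguous length (default 8).
#' @return Named numeric vector `ar.L1`, `ar.L2`, `sigma2`.
#' @export
ar_features <- function(x, min_n = 8L) {
  out <- c(ar.L1 = NA_real_, ar.L2 = NA_real_, sigma2 = NA_real_)
  x <- longest_run(x)
  if (length(x) < min_n || stats::sd(x) == 0) return(out)
  fit <- tryCatch(
    suppressWarnings(
      stats::arima(x, order = c(2L, 0L, 0L), include.mean = TRUE, method = "ML")
    ),
    error = function(e) {
      rlang::warn(paste0("AR(2) fit failed: ", conditionMessage(e)))
      NULL
    }
  )
  if (is.null(fit)) return(out)
  out["ar.L1"] <- unname(fit$coef["ar1"])
  out["ar.L2"] <- unname(fit$coef["ar2"])
  out["sigma2"] <- fit$sigma2
  out
}

# longest contiguous non-missing run (used for spectral and AR features,
# which need an unbroken sampling grid)
longest_run <- function(x) {
  if (length(x) == 0) return(numeric(0))
  ok <- !is.na(x)
  if (!any(ok)) return(numeric(0))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  x[starts[i]:ends[i]]
}

#' All 26 features of one series
#'
#' @param x Numeric monthly series (may contain `NA` for empty months).
#' @return Named numeric vector of length 26, ordered as [feature_names()].
#' @export
series_features <- function(x) {
  c(time_domain_features(x), freq_domain_features(x), ar_features(x))[feature_names()]
}

#' Encode questionnaire responses as feature blocks
#'
#' Likert responses become ordinal integers, binary items 0/1; unanswered
#' items stay missing. One feature per item, named `{block}__{item}`.
#'
#' @param responses Tibble from [generate_questionnaires()] (or the same
#'   schema).
#' @param blocks Survey blocks to include (default: all present).
#' @return Wide tibble, one row per participant.
#' @export
encode_questionnaires <- function(responses, blocks = NULL) {
  known <- questionnaire_items()
  bad <- setdiff(unique(responses$item_id), known$item_id)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown questionnaire item(s): ",
                        paste(bad, collapse = ", ")),
                 class = "phenowear_config_error")
  }
  if (!is.null(blocks)) {
    bad_b <- setdiff(blocks, unique(known$survey_block))
    if (length(bad_b) > 0) {
      rlang::abort(paste0("Unknown survey block(s): ", paste(bad_b, collapse = ", ")),
                   class = "phenowear_config_error")
    }
    responses <- responses |> filter(.data$survey_block %in% blocks)
  }
  responses |>
    mutate(feature = paste0(.data$survey_block, "__", .data$item_id),
           response = as.numeric(.data$response)) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "feature",
                       values_from = "response")
}

#' Build the participant-level feature matrix
#'
#' One row per participant: the 26 features of each (variable, device)
#' monthly series, named `{variable}__{device}__{feature}`, plus optional
#' questionnaire block encodings, and the binary label (1 = IPAH, 0 =
#' disease control or healthy). Phase restriction applies to IPAH rows only
#' (controls have no diagnosis date; all their data are eligible in either
#' phase analysis). Participants with no usable feature are dropped with a
#' message.
#'
#' @param daily Long daily table with a `phase` column.
#' @param participants Roster.
#' @param responses Optional questionnaire responses.
#' @param blocks Optional questionnaire blocks to encode.
#' @param phase `"pre"`, `"post"` or `"all"`.
#' @param device `"phone"`, `"watch"` or `"both"`.
#' @return A list of class `pw_features`: `x` (feature tibble incl.
#'   `participant_id`), `label` (named integer vector), `feature_cols`.
#' @export
build_feature_matrix <- function(daily, participants, responses = NULL,
                                 blocks = NULL, phase = c("all", "pre", "post"),
                                 device = c("both", "phone", "watch")) {
  phase <- match.arg(phase)
  device <- match.arg(device)
  d <- daily
  if (!"phase" %in% names(d)) {
    d <- tag_diagnosis_phase(d, participants)
  }
  if (phase != "all") {
    keep_phases <- c("control", phase)
    d <- d |> filter(.data$phase %in% .env$keep_phases)
  }
  if (device != "both") {
    d <- d |> filter(.data$device == !!device)
  }
  monthly <- monthly_aggregate(d)
  # complete each series over its own month range so internal gaps are
  # explicit NAs
  feats <- monthly |>
    group_by(.data$participant_id, .data$device, .data$variable) |>
    group_modify(function(df, key) {
      months <- seq(min(df$month), max(df$month), by = "month")
      x <- df$value[match(months, df$month)]
      tibble::as_tibble(as.list(series_features(x)))
    }) |>
    ungroup() |>
    tidyr::pivot_longer(cols = dplyr::all_of(feature_names()),
                        names_to = "feature", values_to = "value") |>
    mutate(col = paste0(.data$variable, "__", .data$device, "__", .data$feature)) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "col",
                       values_from = "value")

  if (!is.null(responses)) {
    q <- encode_questionnaires(responses, blocks)
    feats <- left_join(feats, q, by = "participant_id")
  }

  feats <- feats |> semi_join(participants, by = c(participant_id = "id"))
  feature_cols <- setdiff(names(feats), "participant_id")
  usable <- rowSums(!is.na(feats[, feature_cols, drop = FALSE])) > 0
  if (any(!usable)) {
    rlang::inform(sprintf("Dropping %d participant(s) with no usable features.",
                          sum(!usable)))
    feats <- feats[usable, ]
  }
  lab <- setNames(as.integer(participants$group == "IPAH"), participants$id)
  structure(list(x = feats, label = lab[feats$participant_id],
                 feature_cols = feature_cols),
            class = "pw_features")
}

#' @export
print.pw_features <- function(x, ...) {
  cat("<phenowear feature matrix> ", nrow(x$x), " participants x ",
      length(x$feature_cols), " features (", sum(x$label), " IPAH)\n", sep = "")
  invisible(x)
}
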