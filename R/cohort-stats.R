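# Descriptive group-comparison layer: per-variable Mann-Whitney contrasts of
# IPAH against each control group with Benjamini-Hochberg FDR control,
# daily/weekly/seasonal profiling, and the pre/post-diagnosis ANOVA.

#' Compare groups per variable
#'
#' For each variable, participants are summarised (median of their daily
#' values by default, avoiding pseudo-replication of days) and compared with
#' two-sided Mann-Whitney U tests: IPAH vs disease controls and IPAH vs
#' healthy. P-values are Benjamini-Hochberg adjusted across variables within
#' each contrast. Optional covariate adjustment residualises the participant
#' summaries on age, sex, BMI and ethnicity with a linear model before rank
#' testing (an interpretation of "adjusted" rank tests; unadjusted is the
#' default).
#'
#' @param daily Long daily table (`participant_id`, `variable`, `value`, ...).
#' @param participants Roster with `id`, `group` and (for adjustment)
#'   `age_at_consent`, `sex`, `bmi`, `ethnicity`.
#' @param adjust_covariates Residualise on demographics before testing.
#' @param unit `"participant"` (default; participant medians) or `"day"`
#'   (daily values as observations).
#' @param min_per_group Variables with fewer participants than this in any
#'   compared group are skipped with a warning.
#' @return A tibble with group medians and IQRs, adjusted p-values for both
#'   contrasts, and per-group n.
#' @export
compare_groups <- function(daily, participants, adjust_covariates = FALSE,
                           unit = c("participant", "day"), min_per_group = 3L) {
  unit <- match.arg(unit)
  d <- daily |>
    select(-dplyr::any_of(c("group", "age_at_consent", "sex", "bmi", "ethnicity"))) |>
    inner_join(participants |>
                 select(participant_id = "id", "group",
                        dplyr::any_of(c("age_at_consent", "sex", "bmi", "ethnicity"))),
               by = "participant_id")
  summ <- if (unit == "participant") {
    d |>
      group_by(.data$participant_id, .data$group, .data$variable) |>
      summarise(value = stats::median(.data$value, na.rm = TRUE), .groups = "drop") |>
      left_join(participants |>
                  select(participant_id = "id",
                         dplyr::any_of(c("age_at_consent", "sex", "bmi", "ethnicity"))),
                by = "participant_id")
  } else d

  if (adjust_covariates) {
    summ <- summ |>
      group_by(.data$variable) |>
      group_modify(function(df, key) {
        covs <- c("age_at_consent", "sex", "bmi", "ethnicity")
        covs <- covs[vapply(covs, function(cn) {
          cn %in% names(df) && length(unique(stats::na.omit(df[[cn]]))) > 1
        }, logical(1))]
        if (length(covs) == 0) return(df)
        fml <- stats::reformulate(covs, response = "value")
        fit <- stats::lm(fml, data = df, na.action = stats::na.exclude)
        df$value <- stats::residuals(fit)
        df
      }) |>
      ungroup()
  }

  res <- summ |>
    filter(!is.na(.data$value)) |>
    group_by(.data$variable) |>
    group_modify(function(df, key) {
      ns <- table(factor(df$group, levels = c("IPAH", "DC", "Healthy")))
      if (ns["IPAH"] < min_per_group ||
          (ns["DC"] < min_per_group && ns["Healthy"] < min_per_group)) {
        rlang::warn(sprintf("Variable '%s' skipped: group(s) below %d participants.",
                            key$variable, min_per_group))
        return(tibble::tibble())
      }
      mw <- function(g2) {
        if (ns[g2] < min_per_group) return(NA_real_)
        stats::wilcox.test(df$value[df$group == "IPAH"],
                           df$value[df$group == g2],
                           exact = FALSE)$p.value
      }
      qs <- function(g) {
        v <- df$value[df$group == g]
        if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
        stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
      }
      qi <- qs("IPAH"); qd <- qs("DC"); qh <- qs("Healthy")
      tibble::tibble(
        median_IPAH = qi[1], q1_IPAH = qi[2], q3_IPAH = qi[3],
        median_DC = qd[1], q1_DC = qd[2], q3_DC = qd[3],
        median_Healthy = qh[1], q1_Healthy = qh[2], q3_Healthy = qh[3],
        p_IPAH_vs_DC = mw("DC"), p_IPAH_vs_Healthy = mw("Healthy"),
        n_IPAH = as.integer(ns["IPAH"]), n_DC = as.integer(ns["DC"]),
        n_Healthy = as.integer(ns["Healthy"])
      )
    }) |>
    ungroup()
  res$p_adj_IPAH_vs_DC <- stats::p.adjust(res$p_IPAH_vs_DC, method = "BH")
  res$p_adj_IPAH_vs_Healthy <- stats::p.adjust(res$p_IPAH_vs_Healthy, method = "BH")
  res
}

#' Temporal activity/physiology profiles
#'
#' Group mean with a normal-approximation 95% confidence interval per bin of
#' the requested axis (hour of day, weekday, or calendar month). Empty bins
#' are absent.
#'
#' @param metrics Long table with `participant_id`, `variable`, `value`, and
#'   a `date` column (plus `hour` when `axis = "hour"`).
#' @param participants Roster (`id`, `group`).
#' @param axis `"hour"`, `"weekday"` or `"month"`.
#' @return Tibble with `variable`, `group`, `bin`, `mean`, `lo`, `hi`, `n`.
#' @export
temporal_profile <- function(metrics, participants, axis = c("hour", "weekday", "month")) {
  axis <- match.arg(axis)
  d <- metrics |>
    select(-dplyr::any_of("group")) |>
    inner_join(participants |> select(participant_id = "id", "group"),
               by = "participant_id")
  d$bin <- switch(axis,
    hour = {
      if (!"hour" %in% names(d)) {
        rlang::abort("Hourly profile requires an `hour` column.",
                     class = "phenowear_config_error")
      }
      d$hour
    },
    weekday = lubridate::wday(d$date, week_start = 1),
    month = lubridate::month(d$date)
  )
  d |>
    filter(!is.na(.data$value)) |>
    group_by(.data$variable, .data$group, .data$bin) |>
    summarise(
      n = dplyr::n(), mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
    ) |>
    mutate(lo = .data$mean - 1.96 * .data$se, hi = .data$mean + 1.96 * .data$se) |>
    select("variable", "group", "bin", "mean", "lo", "hi", "n")
}

#' Pre- vs post-diagnosis change in IPAH participants
#'
#' One-way ANOVA per variable comparing the 6-month windows immediately
#' before and after diagnosis, on participant-window means. Participants
#' without data in both windows are excluded from that variable's test.
#'
#' @param daily Long daily table with a `phase` column (see
#'   [tag_diagnosis_phase()]).
#' @param participants Roster with `diagnosis_date`.
#' @param window_days Window half-width in days (default 182, ~6 months).
#' @return Tibble with `variable`, `n_participants`, `mean_pre`, `mean_post`,
#'   `direction`, `p_value`.
#' @export
pre_post_change <- function(daily, participants, window_days = 182L) {
  ipah <- participants |> filter(.data$group == "IPAH")
  if (nrow(ipah) == 0) {
    rlang::abort("No IPAH participants in roster.", class = "phenowear_roster_error")
  }
  d <- daily |>
    inner_join(ipah |> select(participant_id = "id", "diagnosis_date"),
               by = "participant_id") |>
    mutate(delta = as.numeric(.data$date - .data$diagnosis_date)) |>
    filter(.data$delta >= -window_days, .data$delta < window_days) |>
    mutate(window = ifelse(.data$delta < 0, "pre", "post"))
  pm <- d |>
    group_by(.data$participant_id, .data$variable, .data$window) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  pm |>
    group_by(.data$variable) |>
    group_modify(function(df, key) {
      both <- df |>
        count(.data$participant_id) |>
        filter(.data$n == 2) |>
        pull(.data$participant_id)
      df <- df |> filter(.data$participant_id %in% both)
      if (length(both) < 2) {
        return(tibble::tibble(n_participants = length(both),
                              mean_pre = NA_real_, mean_post = NA_real_,
                              direction = NA_character_, p_value = NA_real_))
      }
      fit <- stats::aov(value ~ window, data = df)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      mp <- mean(df$value[df$window == "pre"])
      mq <- mean(df$value[df$window == "post"])
      tibble::tibble(n_participants = length(both), mean_pre = mp,
                     mean_post = mq,
                     direction = ifelse(mq > mp, "increase", "decrease"),
                     p_value = p)
    }) |>
    ungroup()
}

#' Plot a temporal profile
#'
#' Ribbon-and-line plot of a [temporal_profile()] result, one panel per
#' variable, coloured by group. Requires ggplot2.
#'
#' @param profile Output of [temporal_profile()].
#' @return A ggplot object.
#' @export
plot_temporal_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("ggplot2 is required for plotting.")
  }
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$mean,
                                        colour = .data$group,
                                        fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "bin", y = "group mean (95% CI)") +
    ggplot2::theme_minimal()
}
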