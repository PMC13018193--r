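#' Questionnaire item definitions
#'
#' The survey blocks administered in the first week after enrolment:
#' a physical-activity readiness screen (`PARQ`, binary items), a life/activity
#' satisfaction block (`Satisfied`, 5-level Likert), cardiovascular risk
#' factors (`RiskFactors`, binary), lifestyle (`Lifestyle`, 4-level Likert),
#' and the exercise-mindset block (`Mindset`, 4-level Likert from
#' "strongly disagree" to "strongly agree").
#'
#' @return A tibble with columns `survey_block`, `item_id`, `type`, `levels`.
#' @export
questionnaire_items <- function() {
  bind_rows(
    tibble::tibble(survey_block = "PARQ",
                   item_id = paste0("parq_q", 1:7),
                   type = "binary", levels = 2L),
    tibble::tibble(survey_block = "Satisfied",
                   item_id = c("sat_life", "sat_activity", "sat_health",
                               "sat_energy", "sat_social"),
                   type = "likert", levels = 5L),
    tibble::tibble(survey_block = "RiskFactors",
                   item_id = c("rf_smoking", "rf_hypertension", "rf_diabetes",
                               "rf_high_cholesterol", "rf_family_cvd",
                               "rf_breathlessness"),
                   type = "binary", levels = 2L),
    tibble::tibble(survey_block = "Lifestyle",
                   item_id = c("ls_diet_quality", "ls_sleep_quality",
                               "ls_alcohol_moderation", "ls_active_commute",
                               "ls_fruit_veg", "ls_nonsmoker"),
                   type = "likert", levels = 4L),
    tibble::tibble(survey_block = "Mindset",
                   item_id = paste0("exercise_",
                                    c("easy", "pleasurable", "relaxing",
                                      "convenient", "fun", "social", "indulgent")),
                   type = "likert", levels = 4L)
  )
}

# Explicitly calibrated Mindset response distributions: the top-level
# ("strongly agree") shares for exercise-is-easy / exercise-is-pleasurable
# are anchored to the published group percentages (Healthy 65/72, DC 55/60,
# IPAH 14/28).
calibrated_item_probs <- function() {
  list(
    exercise_easy = list(
      Healthy = c(0.05, 0.10, 0.20, 0.65),
      DC      = c(0.08, 0.15, 0.22, 0.55),
      IPAH    = c(0.35, 0.30, 0.21, 0.14)
    ),
    exercise_pleasurable = list(
      Healthy = c(0.04, 0.08, 0.16, 0.72),
      DC      = c(0.06, 0.12, 0.22, 0.60),
      IPAH    = c(0.24, 0.26, 0.22, 0.28)
    )
  )
}

#' Generate questionnaire responses for a roster
#'
#' Samples one response per participant and item. The two anchored
#' exercise-mindset items use the calibrated group-specific categorical
#' distributions; all other Likert items discretise a latent normal shifted
#' by the per-group `quest_shift` (IPAH shifted towards less favourable
#' responses); binary items use group-specific probabilities. A small
#' nonresponse rate leaves items missing (no imputation anywhere downstream).
#'
#' @param participants Roster tibble with `id` and `group` columns.
#' @param config A [generator_config()]; `quest_shift` and `seed` are used.
#' @param blocks Optional character vector restricting the survey blocks.
#' @param nonresponse_rate Per-item probability of a missing answer.
#' @return Tibble with `participant_id`, `survey_block`, `item_id`,
#'   `response` (integer; 1..levels for Likert, 0/1 for binary).
#' @export
generate_questionnaires <- function(participants, config = generator_config(),
                                    blocks = NULL, nonresponse_rate = 0.05) {
  items <- questionnaire_items()
  if (!is.null(blocks)) {
    bad <- setdiff(blocks, unique(items$survey_block))
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown survey block(s): ", paste(bad, collapse = ", ")),
                   class = "phenowear_config_error")
    }
    items <- items[items$survey_block %in% blocks, ]
  }
  with_seed(derive_seed(config$seed, "questionnaires"), {
    grid <- tidyr::crossing(participants[, c("id", "group")], items)
    n <- nrow(grid)
    shift <- config$quest_shift[grid$group]
    resp <- integer(n)

    cal <- calibrated_item_probs()
    is_cal <- grid$item_id %in% names(cal)
    if (any(is_cal)) {
      resp[is_cal] <- vapply(which(is_cal), function(i) {
        p <- cal[[grid$item_id[i]]][[grid$group[i]]]
        sample.int(length(p), 1L, prob = p)
      }, integer(1))
    }

    lik <- grid$type == "likert" & !is_cal
    if (any(lik)) {
      L <- grid$levels[lik]
      z <- rnorm(sum(lik)) + shift[lik]
      # equal-mass cut points of the unshifted latent give uniform responses
      # at zero shift
      resp[lik] <- vapply(seq_along(z), function(j) {
        cuts <- qnorm(seq_len(L[j] - 1) / L[j])
        findInterval(z[j], cuts) + 1L
      }, integer(1))
    }

    binr <- grid$type == "binary" & !is_cal
    if (any(binr)) {
      base <- ifelse(startsWith(grid$item_id[binr], "parq"), -2.0, -1.5)
      p <- plogis(base - 1.2 * shift[binr])  # adverse answers more likely when shifted down
      resp[binr] <- as.integer(runif(sum(binr)) < p)
    }

    grid$response <- resp
    grid <- grid[runif(n) >= nonresponse_rate,
                 c("id", "survey_block", "item_id", "response")]
    names(grid)[1] <- "participant_id"
    grid
  })
}
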