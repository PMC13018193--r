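#' Run the end-to-end pipeline
#'
#' Orchestrates simulate -> clean -> metrics -> featurize -> stats -> train
#' (and optionally drift against a drifted external cohort) from a single
#' configuration, writing artifacts and a run manifest with per-stage row
#' and removal counts. One top-level seed fans out to per-stage seeds by
#' stable hashing, so stages are individually reproducible.
#'
#' @param config A [generator_config()], or a path to a YAML file readable by
#'   [read_generator_config()].
#' @param out_dir Output directory for artifacts (created if needed).
#' @param seed Top-level seed (overrides the config seed when given).
#' @param stages Stages to run, in order; `clean` must precede `featurize`.
#' @param device,phase Passed to [build_feature_matrix()].
#' @param blocks Questionnaire blocks to include as features (NULL = none).
#' @param with_us Also simulate the drifted external cohort and run the
#'   drift stage.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = tempfile("pwrun"),
                         seed = NULL,
                         stages = c("simulate", "clean", "metrics", "featurize",
                                    "stats", "train"),
                         device = "both", phase = "pre", blocks = NULL,
                         with_us = FALSE) {
  if (is.character(config)) config <- read_generator_config(config)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  known <- c("simulate", "clean", "metrics", "featurize", "stats", "train", "drift")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")),
                 class = "phenowear_config_error")
  }
  if ("featurize" %in% stages && !"clean" %in% stages) {
    rlang::abort("Stage ordering error: `featurize` requires `clean`.",
                 class = "phenowear_config_error")
  }
  if (with_us) stages <- union(stages, "drift")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenowear")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages, out_dir = out_dir, counts = list()
  )
  note <- function(stage, ...) {
    manifest$counts[[stage]] <<- list(...)
  }

  cohort <- generate_cohort(config)
  readr::write_csv(cohort$participants, file.path(out_dir, "participants.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$questionnaires, file.path(out_dir, "questionnaires.csv"),
                   progress = FALSE)
  note("simulate", n_records = nrow(cohort$records),
       n_participants = nrow(cohort$participants))

  cleaned <- clean_records(cohort$records)
  note("clean", n_in = nrow(cohort$records), n_out = nrow(cleaned$records),
       removed = as.list(cleaned$removed))
  stopifnot(nrow(cohort$records) - sum(cleaned$removed) == nrow(cleaned$records))

  daily <- aggregate_records(cleaned$records, "daily")
  metrics <- derive_daily_metrics(cleaned$records, daily)
  metrics <- tag_diagnosis_phase(metrics |> select(-dplyr::any_of(c("group", "phase"))),
                                 cohort$participants)
  readr::write_csv(metrics, file.path(out_dir, "daily_metrics.csv"), progress = FALSE)
  note("metrics", n_daily_rows = nrow(metrics))

  out <- list(manifest = manifest)
  daily_long <- tag_diagnosis_phase(daily, cohort$participants)

  if ("featurize" %in% stages) {
    fm <- build_feature_matrix(daily_long, cohort$participants,
                               responses = if (is.null(blocks)) NULL else cohort$questionnaires,
                               blocks = blocks, phase = phase, device = device)
    readr::write_csv(fm$x, file.path(out_dir, "features.csv"), progress = FALSE)
    note("featurize", n_participants = nrow(fm$x),
         n_features = length(fm$feature_cols))
    out$features <- fm
  }
  if ("stats" %in% stages) {
    comp <- compare_groups(daily_long, cohort$participants)
    readr::write_csv(comp, file.path(out_dir, "group_comparison.csv"), progress = FALSE)
    note("stats", n_variables = nrow(comp))
    out$comparison <- comp
  }
  if ("train" %in% stages && !is.null(out$features)) {
    cv <- cross_validate(out$features, spec = model_spec(seed = derive_seed(config$seed, "train")),
                         seed = derive_seed(config$seed, "folds"))
    jsonlite::write_json(list(per_fold = cv$per_fold, summary = cv$summary),
                         file.path(out_dir, "cv_result.json"), dataframe = "rows")
    note("train", auc_mean = cv$summary$mean[cv$summary$metric == "auc"])
    out$cv <- cv
  }
  if ("drift" %in% stages) {
    us <- generate_us_cohort(config)
    us_clean <- clean_records(us$records)
    us_daily <- tag_diagnosis_phase(aggregate_records(us_clean$records, "daily"),
                                    us$participants)
    us_fm <- build_feature_matrix(us_daily, us$participants,
                                  phase = phase, device = device)
    dr <- drift_report(out$features, us_fm)
    readr::write_csv(dr, file.path(out_dir, "drift_report.csv"), progress = FALSE)
    note("drift", n_features = nrow(dr), max_psi = max(dr$psi, na.rm = TRUE))
    out$drift <- dr
  }

  manifest$counts <- manifest$counts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
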