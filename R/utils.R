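# Internal helpers shared across modules.

# Columns that define a record's identity; the internal contamination label
# (`injected`) is deliberately excluded so cleaning never keys on it.
record_schema_cols <- function() {
  c("participant_id", "variable", "value", "unit",
    "start_time", "end_time", "device", "region")
}

#' Derive a stage-specific seed from a top-level seed
#'
#' One run-level seed fans out deterministically to per-stage seeds so that
#' adding or reordering downstream stages never perturbs upstream randomness.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer top-level seed.
#' @param stage Character scalar naming the stage (e.g. `"simulate"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    rlang::abort(sprintf("`%s` must lie in [0, 1].", name), class = "phenowear_config_error")
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be positive and finite.", name), class = "phenowear_config_error")
  }
  invisible(x)
}
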