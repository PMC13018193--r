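# Cohort drift monitoring with the Population Stability Index, and the
# transfer-learning mix-in experiment (train on UK plus a fraction of the
# external cohort, test on the held-out remainder).

#' Population Stability Index between two samples
#'
#' The pooled value range is segmented into `n_buckets` equal-width bins;
#' for each bin the difference between the expected (reference) and actual
#' proportions is multiplied by the natural log of their ratio and the
#' per-bucket contributions are summed:
#' `PSI = sum_b (p_e,b - p_a,b) * ln(p_e,b / p_a,b)`.
#' Zero-count buckets are stabilised by adding `eps` to each proportion and
#' renormalising. PSI is non-negative and symmetric in its arguments.
#'
#' @param expected,actual Numeric samples (reference and comparison).
#' @param n_buckets Number of equal-width buckets (default 10).
#' @param eps Stabiliser added to bucket proportions (default 1e-4).
#' @return A list of class `pw_psi`: `psi`, `breaks`, `expected_prop`,
#'   `actual_prop`, `n_buckets`.
#' @export
psi <- function(expected, actual, n_buckets = 10L, eps = 1e-4) {
  expected <- expected[is.finite(expected)]
  actual <- actual[is.finite(actual)]
  if (length(expected) == 0 || length(actual) == 0) {
    rlang::abort("Both samples must be non-empty.", class = "phenowear_psi_error")
  }
  rng <- range(c(expected, actual))
  if (diff(rng) == 0) {
    rlang::warn("Constant pooled range; PSI is 0.")
    return(structure(list(psi = 0, breaks = rng,
                          expected_prop = 1, actual_prop = 1,
                          n_buckets = 1L), class = "pw_psi"))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_buckets + 1L)
  cut_ <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = n_buckets)
  }
  pe <- cut_(expected) / length(expected)
  pa <- cut_(actual) / length(actual)
  val <- psi_from_props(pe, pa, eps)
  structure(list(psi = val, breaks = breaks, expected_prop = pe,
                 actual_prop = pa, n_buckets = n_buckets), class = "pw_psi")
}

#' PSI from pre-computed bucket proportions
#'
#' @param expected_prop,actual_prop Proportion vectors (each summing to 1).
#' @param eps Stabiliser for zero proportions.
#' @return The PSI value.
#' @export
psi_from_props <- function(expected_prop, actual_prop, eps = 1e-4) {
  stopifnot(length(expected_prop) == length(actual_prop))
  p <- expected_prop + eps
  q <- actual_prop + eps
  p <- p / sum(p)
  q <- q / sum(q)
  sum((p - q) * log(p / q))
}

#' @export
print.pw_psi <- function(x, ...) {
  cat(sprintf("<PSI> %.4f over %d buckets\n", x$psi, x$n_buckets))
  invisible(x)
}

#' Per-feature drift report between two feature matrices
#'
#' Computes the PSI of every shared feature column and ranks features by
#' drift. Flag thresholds (0.1 "watch", 0.25 "act") follow the common
#' industry convention for PSI monitoring.
#'
#' @param features_a,features_b `pw_features` objects (or plain data frames
#'   of numeric columns); `features_a` is the expected/reference side.
#' @param n_buckets,eps Passed to [psi()].
#' @return Tibble `feature`, `psi`, `flag`, sorted by decreasing PSI.
#' @export
drift_report <- function(features_a, features_b, n_buckets = 10L, eps = 1e-4) {
  xa <- if (inherits(features_a, "pw_features")) features_a$x[features_a$feature_cols] else features_a
  xb <- if (inherits(features_b, "pw_features")) features_b$x[features_b$feature_cols] else features_b
  shared <- intersect(names(xa), names(xb))
  shared <- shared[vapply(xa[shared], is.numeric, logical(1))]
  if (length(shared) == 0) {
    rlang::abort("No shared feature columns.", class = "phenowear_psi_error")
  }
  vals <- vapply(shared, function(cn) {
    a <- xa[[cn]][is.finite(xa[[cn]])]
    b <- xb[[cn]][is.finite(xb[[cn]])]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    suppressWarnings(psi(a, b, n_buckets, eps)$psi)
  }, numeric(1))
  tibble::tibble(feature = shared, psi = unname(vals)) |>
    mutate(flag = dplyr::case_when(
      .data$psi >= 0.25 ~ "act",
      .data$psi >= 0.10 ~ "watch",
      TRUE ~ "stable"
    )) |>
    arrange(dplyr::desc(.data$psi))
}

#' Transfer-learning mix-in experiment
#'
#' For each mix fraction `f`: a stratified sample of `f` of the external
#' cohort's participants is added to the full home-cohort training set; the
#' model is trained with participant-level k-fold cross-validation on the
#' combined set and each fold's model is evaluated on the held-out external
#' participants (never including any mixed-in participant — the leakage
#' certificate records this). `f = 0` reproduces plain external validation.
#'
#' @param uk_features,us_features `pw_features` objects sharing columns
#'   (home and external cohorts).
#' @param fractions Mix fractions in `[0, 1)`.
#' @param spec A [model_spec()].
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed (controls the mix-in sampling and folds).
#' @return A tibble of class `pw_mixin`: per fraction, the external-test AUC
#'   mean/SD across fold models, train composition, and the leakage
#'   certificate.
#' @export
transfer_mixin <- function(uk_features, us_features,
                           fractions = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                           spec = model_spec(), k = 5L, seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions < 1))
  shared <- intersect(uk_features$feature_cols, us_features$feature_cols)
  if (length(shared) == 0) {
    rlang::abort("Cohorts share no feature columns.", class = "phenowear_psi_error")
  }
  uk_m <- as_feature_matrix(uk_features)[, shared, drop = FALSE]
  us_m <- as_feature_matrix(us_features)[, shared, drop = FALSE]
  uk_y <- uk_features$label
  us_y <- us_features$label
  us_ids <- rownames(us_m)

  rows <- list()
  for (f in fractions) {
    mix_ids <- if (f == 0) character(0) else with_seed(
      derive_seed(seed, paste0("mixin-", f)), {
        unlist(lapply(split(us_ids, us_y[us_ids]), function(ids) {
          sample(ids, round(f * length(ids)))
        }), use.names = FALSE)
      })
    test_ids <- setdiff(us_ids, mix_ids)
    if (sum(us_y[test_ids] == 1) < 2 || sum(us_y[test_ids] == 0) < 2) {
      rlang::warn(sprintf("Fraction %.2f skipped: <2 test participants per class.", f))
      next
    }
    assert_no_leakage(mix_ids, test_ids)
    train_m <- rbind(uk_m, us_m[mix_ids, , drop = FALSE])
    train_y <- c(uk_y, us_y[mix_ids])
    names(train_y) <- rownames(train_m)

    folds <- with_seed(derive_seed(seed, paste0("folds-", f)), {
      fd <- integer(nrow(train_m))
      for (cl in unique(train_y)) {
        i <- which(train_y == cl)
        fd[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      fd
    })
    aucs <- c()
    for (fold in seq_len(k)) {
      tr <- rownames(train_m)[folds != fold]
      if (length(unique(train_y[tr])) < 2) next
      model <- train_model(train_m[tr, , drop = FALSE], train_y, spec)
      sc <- predict_scores(model, us_m[test_ids, , drop = FALSE])
      aucs <- c(aucs, auc_score(us_y[test_ids], sc))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      fraction = f,
      n_train_uk = nrow(uk_m), n_train_mix = length(mix_ids),
      n_test = length(test_ids),
      auc_mean = mean(aucs, na.rm = TRUE),
      auc_sd = stats::sd(aucs, na.rm = TRUE),
      leakage_free = length(intersect(mix_ids, test_ids)) == 0
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("pw_mixin", class(out))
  out
}
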