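# Classifier protocol: splits, leakage guard, thresholds, training,
# importance.

make_labels <- function(n_pos, n_neg) {
  setNames(c(rep(1L, n_pos), rep(0L, n_neg)),
           sprintf("P%03d", seq_len(n_pos + n_neg)))
}

synth_features <- function(labels, n_feat = 5, sep = 0, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  m <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(names(labels), paste0("f", seq_len(n_feat))))
  m[, 1] <- m[, 1] + sep * labels
  x <- tibble::as_tibble(m)
  x$participant_id <- names(labels)
  structure(list(x = x[, c("participant_id", colnames(m))], label = labels,
                 feature_cols = colnames(m)), class = "pw_features")
}

test_that("stratified split gives documented counts and is deterministic", {
  labels <- make_labels(10, 20)
  sp <- split_participants(labels, 0.7, seed = 4L)
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(sum(labels[sp$train]), 7L)
  expect_identical(sum(labels[sp$test]), 3L)
  expect_identical(sum(labels[sp$train] == 0), 14L)
  sp2 <- split_participants(labels, 0.7, seed = 4L)
  expect_identical(sp, sp2)
  expect_error(split_participants(make_labels(1, 5)),
               class = "phenowear_split_error")
})

test_that("the leakage guard rejects contaminated splits", {
  expect_error(assert_no_leakage(c("A", "B"), c("B", "C")),
               class = "phenowear_leakage_error")
  expect_true(assert_no_leakage(c("A", "B"), c("C")))
})

test_that("threshold selection equals brute-force grid search", {
  set.seed(33)
  for (i in 1:25) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    scores <- runif(n)
    got <- choose_threshold(scores, labels)
    grid <- seq(0, 1, 0.1)
    f1s <- sapply(grid, function(th) {
      yhat <- as.integer(scores >= th)
      tp <- sum(labels & yhat); fp <- sum(!labels & yhat); fn <- sum(labels & !yhat)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    })
    expect_identical(got, grid[which.max(f1s)])
  }
})

test_that("threshold edge cases follow the documented rules", {
  # perfectly separated scores: F1 = 1 from 0.2 up; ties -> lowest
  scores <- c(0.1, 0.12, 0.15, 0.9, 0.92, 0.95)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(choose_threshold(scores, labels), 0.2)
  # all-positive labels: recall-driven F1 maximal at threshold 0
  expect_equal(choose_threshold(c(0.2, 0.6, 0.9), c(1, 1, 1)), 0)
  expect_warning(th <- choose_threshold(rep(0.4, 5), c(0, 1, 0, 1, 0)))
  expect_equal(th, 0.5)
})

test_that("training is deterministic and robust to duplicated rows", {
  labels <- make_labels(12, 24)
  feats <- synth_features(labels, sep = 2, seed = 7)
  spec <- model_spec(seed = 5L)
  m1 <- train_model(feats, labels, spec)
  m2 <- train_model(feats, labels, spec)
  expect_identical(predict_scores(m1, feats), predict_scores(m2, feats))
  dup <- feats
  dup$x <- dplyr::bind_rows(dup$x, dup$x[1, ])
  dup$x$participant_id[nrow(dup$x)] <- "P999"
  dup_labels <- c(labels, P999 = labels[[1]])
  expect_no_error(train_model(dup, dup_labels, spec))
  expect_error(train_model(feats, setNames(rep(1L, 36), names(labels)), spec),
               class = "phenowear_fit_error")
})

test_that("an informative feature dominates gain importance", {
  labels <- make_labels(15, 30)
  feats <- synth_features(labels, n_feat = 6, sep = 3, seed = 9)
  fit <- train_model(feats, labels, model_spec(seed = 2L))
  imp <- feature_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-8)
  expect_identical(imp$feature[1], "f1")
  svm_fit <- train_model(feats, labels, model_spec("svm", seed = 2L))
  expect_error(feature_importance(svm_fit), class = "phenowear_config_error")
})

test_that("cross-validation partitions participants and reports both models", {
  labels <- make_labels(14, 28)
  feats <- synth_features(labels, sep = 2.5, seed = 21)
  cv <- cross_validate(feats, spec = model_spec(seed = 3L), seed = 6L)
  expect_identical(nrow(cv$per_fold), 5L)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_gt(cv$summary$mean[cv$summary$metric == "auc"], 0.8)
  expect_true(all(cv$per_fold$n_test_pos + cv$per_fold$n_test_neg > 0))
  cv_svm <- cross_validate(feats, spec = model_spec("svm", seed = 3L), seed = 6L)
  expect_gt(cv_svm$summary$mean[cv_svm$summary$metric == "auc"], 0.8)
})

test_that("a perfectly separable feature yields AUC 1 in every fold", {
  labels <- make_labels(10, 20)
  x <- tibble::tibble(participant_id = names(labels),
                      f1 = as.numeric(labels))
  feats <- structure(list(x = x, label = labels, feature_cols = "f1"),
                     class = "pw_features")
  cv <- cross_validate(feats, spec = model_spec(seed = 1L), seed = 2L)
  expect_true(all(cv$per_fold$auc == 1))
})

test_that("permuted labels give chance-level AUC", {
  labels <- make_labels(12, 24)
  feats <- synth_features(labels, sep = 2, seed = 13)
  m <- phenowear:::as_feature_matrix(feats)
  set.seed(55)
  aucs <- replicate(30, {
    perm <- setNames(sample(labels), names(labels))
    sp <- split_participants(perm, 0.7, seed = sample.int(1e6, 1))
    fit <- train_model(feats, perm, model_spec(seed = 1L), ids = sp$train)
    sc <- predict_scores(fit, feats, ids = sp$test)
    phenowear:::auc_score(perm[names(sc)], sc)
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.07)
})

test_that("cross-validated signal on the synthetic cohort clears chance", {
  fx <- shared_model_features()
  cv <- cross_validate(fx$fm_uk, spec = model_spec(seed = 8L), seed = 9L)
  expect_gt(cv$summary$mean[cv$summary$metric == "auc"], 0.6)
})

test_that("stronger group separation never hurts cross-validated AUC", {
  aucs <- sapply(c(1.0, 0.6, 0.3), function(mult) {
    gp <- default_group_params()
    sel <- gp$group == "IPAH" & gp$class == "activity"
    gp$p1[sel] <- gp$p1[sel] * ifelse(grepl("Pace", gp$variable[sel]), 1, mult)
    cfg <- generator_config(
      n_per_group = c(IPAH = 12L, DC = 6L, Healthy = 18L), date_span = 360L,
      group_params = gp, variables = c("stepCount", "flightsClimbed"),
      seed = 404L
    )
    co <- generate_cohort(cfg, output = "daily")
    fm <- build_feature_matrix(co$daily, co$participants,
                               phase = "all", device = "phone")
    cv <- cross_validate(fm, spec = model_spec(seed = 1L), seed = 2L)
    cv$summary$mean[cv$summary$metric == "auc"]
  })
  expect_true(!is.unsorted(aucs))  # smaller IPAH multiplier = larger separation
})
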