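# phenowear

Digital phenotyping of smartphone and smartwatch data streams for idiopathic
pulmonary arterial hypertension (IPAH) risk.

IPAH is a rare, progressive disease of the pulmonary circulation that is
typically diagnosed late, by invasive right-heart catheterisation, because
its early symptoms are non-specific. Passively collected wearable data —
step counts, stair climbs, walking pace, PPG-derived heart rate and
heart-rate variability, estimated VO₂max, sleep states — carry an early
functional signature of the disease and are candidate digital biomarkers for
earlier detection and remote monitoring. `phenowear` is an R package for
researchers working with such HealthKit-style record streams: it implements
the full analysis chain from raw records to a cross-validated classifier and
cross-cohort drift monitoring, together with a calibrated synthetic cohort
generator so that every stage is testable without access to patient data.

## What the package does

* **Synthetic cohorts** (`generate_cohort()`, `generate_us_cohort()`,
  `generate_questionnaires()`) — seed-reproducible participants (IPAH,
  disease control, healthy), raw phone/watch record streams and
  questionnaire responses, calibrated to published group-level statistics:
  lognormal daily counts (median/IQR-matched), truncated-Gaussian heart
  rates, circadian/weekly/seasonal modulation, a post-diagnosis recovery
  effect, injected contamination (15% exact duplicates, 13.7% out-of-bounds
  outliers, invalid rows, short and month-long gaps) and a UK-vs-US regional
  drift.
* **Record store** (`read_records()`, `clean_records()`,
  `aggregate_records()`, `tag_diagnosis_phase()`) — CSV/JSONL IO, exact
  duplicate removal, daily-plausibility outlier bounds, invalid-row
  handling, hourly/daily per-device aggregation, pre/post-diagnosis
  tagging. No imputation anywhere.
* **Derived metrics** (`derive_daily_metrics()`) — interval gait/climb paces
  with daily mean/max (the 0.5 s exclusion rule), heart-rate reserve
  (average − resting HR), cardiac effort (walking HR / walking speed), the
  bed-bound flag (≥ 18 h/day in bed), and the duration-weighted fraction of
  active time above 70% of maximum pace.
* **Cohort statistics** (`compare_groups()`, `temporal_profile()`,
  `pre_post_change()`) — Mann–Whitney group contrasts with
  Benjamini–Hochberg FDR control, daily/weekly/seasonal profiles with 95%
  CIs, and the pre/post-diagnosis ANOVA.
* **Featurization** (`build_feature_matrix()`) — monthly aggregation and 26
  time-domain, frequency-domain and AR(2) features per (variable, device)
  series (`N`, `MAX`, `MIN`, `P2P`, `RMS`, `STD`, `VAR`, `MEAN`, `PEAK`,
  `SKEW`, `KURTOSIS`, `CREST_FACTOR`, `cc_lag0..2`, `MAX_f`, `MEAN_f`,
  `VAR_f`, `SUM_f`, `PEAK_f`, `SKEW_f`, `KURTOSIS_f`, `POWER`, `ar.L1`,
  `ar.L2`, `sigma2`), plus ordinal questionnaire block encodings.
* **Classification** (`cross_validate()`, `train_model()`) — IPAH vs
  combined controls with gradient-boosted trees (fixed hyperparameters:
  reg_alpha 2, reg_lambda 5, learning rate 0.07, depth 6, 30 rounds) or a
  linear SVM; participant-level stratified splits with a leakage guard,
  five-fold CV, F1-optimal thresholds on a 0.1 grid, gain-based feature
  importance.
* **Drift monitoring** (`psi()`, `drift_report()`, `transfer_mixin()`) — the
  Population Stability Index, PSI = Σ (p_e − p_a)·ln(p_e/p_a) over
  equal-width value buckets, per-feature drift ranking, and the
  transfer-learning mix-in experiment (train on the home cohort plus a
  fraction of the external cohort, test on the held-out remainder).
* **Orchestration** (`run_pipeline()`) — one-config end-to-end runs with a
  manifest of per-stage row and removal counts.

## Worked example

```r
library(phenowear)

cfg <- generator_config(n_per_group = c(IPAH = 15L, DC = 8L, Healthy = 25L),
                        date_span = 540L, seed = 7L)
cohort <- generate_cohort(cfg)
cohort
#> <phenowear synthetic cohort>
#>   participants: 48 (DC=8, Healthy=25, IPAH=15)
#>   records:      959642
#>   questionnaire responses: 1414

cleaned <- clean_records(cohort$records)
cleaned$removed
#>   invalid duplicate   outlier
#>        82    143946    111746
```

Cleaning removed 143,946 exact duplicates (15.0% of the stream) and 111,746
out-of-bounds records (13.7% of the deduplicated stream) — the generator's
injected contamination, recovered exactly.

```r
daily <- tag_diagnosis_phase(aggregate_records(cleaned$records, "daily"),
                             cohort$participants)
comp <- compare_groups(daily, cohort$participants)
comp[comp$variable %in% c("stepCount", "heartRateVariabilitySDNN"),
     c("variable", "median_IPAH", "median_Healthy", "p_adj_IPAH_vs_Healthy")]
#> # A tibble: 2 × 4
#>   variable                 median_IPAH median_Healthy p_adj_IPAH_vs_Healthy
#> 1 heartRateVariabilitySDNN        30.0           38.1           0.000000245
#> 2 stepCount                     4310           5918.            0.000000245
```

IPAH participants take fewer daily steps and show lower heart-rate
variability than healthy controls (participant-median Mann–Whitney tests,
BH-adjusted). The pooled medians sit at the calibrated group levels.

```r
fm <- build_feature_matrix(daily, cohort$participants,
                           phase = "pre", device = "watch")
cv <- cross_validate(fm, spec = model_spec(seed = 1L), seed = 2L)
cv
#> <phenowear cross-validation> 5/5 folds
#>   auc       1.000 +/- 0.000
#>   f1        1.000 +/- 0.000
#>   precision 1.000 +/- 0.000
#>   recall    1.000 +/- 0.000
```

On pre-diagnosis watch features of this synthetic cohort the classifier
separates the groups essentially perfectly — the generator's group effects
are strong and its days are independent, so synthetic performance says
nothing about real-world accuracy; it verifies the protocol (participant-level
folds, no leakage, threshold selection), not the clinical claim.

## Notes

* The methods vignette (`vignettes/phenowear-methods.Rmd`) documents the
  generative model, every calibration constant, the numerical conventions
  of the feature set, and known limitations.
* Published classification results on real patient cohorts are **not**
  reproduction targets of this package; real data of this kind are not
  publicly available.
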