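---
title: "Digital phenotyping of wearable streams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of wearable streams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenowear)
```

## The problem

Idiopathic pulmonary arterial hypertension (IPAH) is a rare, progressive
disease that is usually diagnosed years after first symptoms, by invasive
right-heart catheterisation. Because reduced exercise capacity appears early,
passively collected smartphone and smartwatch data — step counts, stair
climbs, walking pace, photoplethysmography-derived heart rate, heart-rate
variability, estimated VO~2~max, and sleep states — are candidate digital
biomarkers for earlier detection and remote monitoring.

`phenowear` implements the full analysis chain for such data: cleaning of raw
HealthKit-style records, derived gait and cardiac metrics, descriptive group
comparisons, participant-level featurization, a cross-validated binary
classifier of IPAH against combined disease and healthy controls, drift
monitoring between cohorts with the Population Stability Index (PSI), and a
transfer-learning mix-in protocol. Since real patient streams of this kind
are not publicly distributable, the package ships a calibrated synthetic
cohort generator as a first-class, tested module: every downstream stage is
exercised end-to-end on generated data.

## The synthetic cohort generator

`generate_cohort()` draws three groups — IPAH cases, disease controls (DC)
and healthy controls — with a default roster of 30/15/60 participants
(configurable), mirroring the proportions of the cohort the generator
emulates, each observed for `date_span` days (default 365).

**Daily distributions.** For every (variable, device, group) combination the
generator draws daily values from a calibrated distribution
(`default_group_params()`):

* count-like and duration-like variables (steps, flights, distance, energy,
  stand time, sleep states) are lognormal, with the median set to the
  published group median and the log-scale sd fitted from the published
  interquartile range as `log(Q3/Q1)/1.349`. Where only a mean ± SD is
  published (flights climbed), the lognormal is moment-matched.
* heart-rate-like variables (resting/average/walking heart rate, VO~2~max)
  are Gaussian, truncated to physiological envelopes (e.g. 20–250 beats/min).
* heart-rate variability (SDNN) is kept lognormal rather than Gaussian: SDNN
  is strictly positive and its published IQR is clearly right-skewed, and a
  Gaussian truncated at zero would displace the median away from the
  published value.

The calibration anchors are the published group tables: e.g. daily phone step
count medians 4620 (healthy), 3323 (DC), 2596 (IPAH, treated as the
pre-diagnosis level); watch resting heart rate 62 beats/min (healthy); SDNN
29.93 ms (IPAH); VO~2~max 37.4 mL O~2~/kg/min (healthy); nightly awake time
with median 0.41 h and an IQR-implied lognormal mean of ~1 h for IPAH against
~0.24 h for healthy controls. Fitting the awake-time scale from the IQR gives
a mean of ~59 min where ~56 min is reported — one lognormal cannot match both
printed quantities exactly; we keep the uniform IQR rule and accept the ~6%
discrepancy.

**Effect directions** are fixed by construction: IPAH sits below healthy for
step count, paces, flights, SDNN and VO~2~max, and above healthy for walking
heart rate and nocturnal awake time. A property test verifies the sign
pattern with Mann–Whitney tests at 30 participants per group.

**Within-day structure.** Activity is emitted as variable-count intervals.
For each day the generator draws the daily total `D` and the day's maximum
interval pace `M` (itself lognormal, calibrated per group and device), then
splits `D` across `k ~ 1 + Poisson` intervals whose start hours follow a
24-value circadian weight profile. The largest interval carries pace exactly
`M` and the others uniform fractions of it, so the daily maximum pace
recovered by the pace pipeline reproduces the configured lognormal exactly,
and the daily mean-to-max pace ratio (~0.35) matches the published ratios
(~0.32–0.39). Interval durations follow as `steps/pace`, which keeps daily
sums exactly conserved — the aggregation mass-conservation test relies on
this.

**Pace pooling calibration.** The published per-group pace medians and the
published pooled UK median of the daily maximum step pace (112 steps/min) are
mutually inconsistent by about 7% under any mixture of the per-group
lognormals. Because the pooled value is the quantity the external-drift
comparison is anchored to, the generator applies a single `pace_calibration`
factor (default 1.029, measured once from the mixture median of the default
configuration) to all pace medians, preserving every group ratio and
direction while placing the pooled median at 112.

**Modulation.** Weekend effects are applied as a median-preserving weekly
contrast: with ratio `m` (default 0.85 for healthy, 0.9 DC, 1.0 IPAH — the
healthy weekend dip), weekend days are multiplied by `m^(5/7)` and weekdays
by `m^(-2/7)`, so the weekend:weekday ratio is exactly `m` while the pooled
median is untouched. Seasonal modulation multiplies activity by
`exp(A sin(2π(doy - 105)/365.25))` (default `A = 0.08`, peak in July), which
is symmetric on the log scale and therefore also median-neutral. The
circadian profile only shapes within-day allocation. IPAH participants
switch to post-diagnosis parameters on the diagnosis date: activity ×1.3
(treatment response) and heart rates ×0.95, as a step change — a deliberate
simplification that makes the pre/post ANOVA exactly testable.

**Contamination** is injected *on top of* the clean signal, never by
corrupting it, so a correct cleaning stage recovers exactly the clean stream
and recall/precision can be computed from the internal `injected` labels:

* exact duplicates: appended copies sized so they form 15% of the emitted
  stream (deduplication therefore removes 15% of input rows);
* out-of-bounds rows: appended copies with values pushed beyond the
  daily-plausibility upper bound, sized to 13.7% of the post-dedup stream;
* invalid rows: non-finite values or pre-epoch dates at a 0.01% rate;
* gaps: per-day dropouts (8%) and whole missing calendar months (3% of
  participant-months), the latter matching the month-long gaps such studies
  report.

**Regional drift.** `generate_us_cohort()` applies per-variable multipliers
to the distribution locations: 86/112 (the ratio of the published US and UK
pooled maximum-pace medians) for pace variables and 0.75 for activity
volumes; heart-rate and sleep variables are left undrifted. Directions of
group differences are conserved under any positive multiplier.

**What the generator does not emulate.** Raw accelerometer/PPG waveforms,
auto-correlated day-to-day behaviour (days are conditionally independent
given the modulation curves), device non-wear biased by disease severity,
clinical variables, and realistic questionnaire item correlation structure.
Passing tests therefore demonstrate pipeline correctness and calibration
fidelity, not clinical performance on real cohorts; the published
classification AUCs on real data are explicitly not reproduction targets.

## Cleaning

The chain is `drop_invalid()` → `deduplicate()` → `filter_outliers()`.
Duplicates are exact matches on all schema fields. The outlier rule is
per-record against per-day plausibility bounds (`default_bounds()`): a single
record whose value could not be achieved within one day (e.g. 250,000 steps)
is an artefact. Default bounds are generous physiological envelopes
(steps ≤ 100,000/day, heart rates 20–250 beats/min, HRV ≤ 500 ms, sleep
0–24 h) and fully configurable; they are the package's own defaults. Invalid
rows are non-finite values, unparseable or reversed timestamps, pre-1970
dates, or dates outside an optional study window. No imputation anywhere:
missing stays missing. The chain is idempotent and dedup/outlier filtering
commute, both property-tested.

Aggregation sums counts, averages rates and sums sleep durations per
participant-day(-hour)-device; a record belongs to the local-midnight day of
its start time; phone and watch are never merged (the reconciliation policy
for same-day dual-device step counts is deliberately not defined). Days with
no records are absent, not zero. Diagnosis-day rows count as *post*
(treatment can start the same day); the boundary is configurable by
filtering on `date` directly.

## Derived metrics

Per day and device, from cleaned records:

* interval pace = count / duration (per minute), excluding intervals shorter
  than 0.5 s; daily mean and maximum per activity (steps, flights);
* heart-rate reserve = average − resting heart rate (negatives retained,
  flagged);
* cardiac effort = walking heart rate / walking speed, speed in m/s by
  default (units configurable; the daily walking duration is the summed
  step-interval time) — the heart-rate-per-speed formulation is used
  throughout; an average-heart-rate-over-active-time variant is deliberately
  not implemented;
* bed-bound flag: time in bed ≥ 18 h/day;
* fraction of active time above 70% of maximum pace: duration-weighted, with
  the reference maximum taken over all of a participant's intervals in the
  observation period by default (`pmax_scope = "day"` switches to the day's
  own maximum; the scope of "maximum effort" is a genuine modelling choice
  and both readings are supported).

Every formula is pinned against an independent, loop-based oracle
implementation on 1000 random fixture days at 1e-10 tolerance.

## Group statistics

`compare_groups()` tests IPAH against each control group per variable with
two-sided Mann–Whitney U tests and Benjamini–Hochberg adjustment across
variables. The unit of analysis defaults to participant medians of daily
values — testing days directly would pseudo-replicate within-person
correlation; a `unit = "day"` mode is provided for sensitivity analyses.
"Covariate-adjusted" rank testing is interpreted as
residualising participant summaries on age, sex, BMI and ethnicity with a
linear model before rank testing; unadjusted is the default.
`temporal_profile()` returns group means with normal-approximation 95% CIs
by hour, weekday or month. `pre_post_change()` runs a one-way ANOVA on
participant-window means across the 6-month windows flanking diagnosis.

## Featurization

Daily values are averaged into calendar months per participant, variable and
device (pre-diagnosis filtering applies to cases only; controls, having no
diagnosis date, contribute all months to either phase analysis). Each
monthly series yields 26 features:

* time domain (missing months dropped, series compacted): `N`, `MAX`, `MIN`,
  `P2P`, `MEAN`, sample (`N−1`) `VAR`/`STD`, `RMS`, `PEAK` (max absolute),
  `CREST_FACTOR` (PEAK/RMS), `SKEW` and excess `KURTOSIS` (standardised
  central moments with population denominators), and `cc_lag0..2`, read as
  sample autocorrelation at lags 0–2 (a documented convention of this
  package);
* frequency domain (longest contiguous run, ≥4 months): magnitude spectrum
  of the mean-centred series excluding the DC bin; `MAX_f`, `MEAN_f`,
  `VAR_f`, `SUM_f`, `PEAK_f`, `SKEW_f`, `KURTOSIS_f` are the time-domain
  statistics of that spectrum, and `POWER = Σ|F_k|²/(N(N−1))`, normalised so
  that by Parseval's identity it equals the sample variance — an exact,
  test-pinned identity;
* autoregressive (longest contiguous run, ≥8 months): `ar.L1`, `ar.L2`,
  `sigma2` from an AR(2)-with-intercept maximum-likelihood fit
  (`stats::arima`); non-convergent fits yield missing values. Order 2 with
  intercept is the documented specification, matching the three named AR
  outputs.

Features below their minimum length are missing, never fabricated. Column
naming is stable: `{variable}__{device}__{feature}` and `{block}__{item}`
for questionnaire encodings (Likert → ordinal integers, binary → 0/1,
unanswered → missing).

## Classification

Binary label: IPAH = 1 versus combined DC + healthy = 0. Splits and folds are
always at the participant level, stratified by label, and a leakage guard
(`assert_no_leakage()`) rejects any partition that shares a participant.
The gradient-boosted-tree model uses the fixed published hyperparameters
(reg_alpha 2, reg_lambda 5, learning rate 0.07, depth 6, 30 rounds) and
handles missing features natively. The class weight defaults
to 2 — the minority-class-upweighting member of the documented `{2, 0.5}`
candidate pair; 0.5 is exposed as the alternative.
The linear SVM variant standardises features and imputes with training-fold
medians (a preprocessing convention of this package, required for margin
models). Thresholds are picked on a 0.1 grid by maximal F1 — computed on the
training scores of each fold and applied to its test fold; ties resolve to
the lower threshold. Metrics (ROC AUC via `pROC`, F1, precision, recall) are
aggregated as mean ± SD across five folds.

## Drift monitoring and the mix-in experiment

The PSI between a reference and a comparison sample segments the pooled
value range into 10 equal-width buckets and sums
`(p_e − p_a) · ln(p_e/p_a)`; each term is non-negative and the statistic is
symmetric, both property-tested, and a two-bucket hand-computed case
(0.5/0.5 vs 0.25/0.75 → 0.27465) is pinned exactly. Zero-count buckets are
stabilised by adding ε = 1e-4 and renormalising (a package convention; ε is
configurable). The monitoring flags (0.1 watch, 0.25 act) follow the common
industry custom for PSI.

`transfer_mixin()` adds a stratified fraction *f* of the external cohort's
participants to the home training set, cross-validates on the combined set,
and evaluates every fold model on the held-out external participants; mixed-in
participants are certified absent from the test set. With the default drifted
generator and phone-only (all-drifted) features, the UK-trained model
degrades on the US cohort — tree splits learned on the UK range saturate on
uniformly down-shifted US values — and mixing in 20% restores most of the
performance, with little further gain beyond 20%: the qualitative finding
the acceptance suite verifies by a sign test over 20 paired-seed replicates.
The replicate size (15/8/25 per group, 540 days) was chosen by a power
argument: external test sets of ≥12 cases / 24 controls keep per-replicate
AUC noise near 0.05 against an expected improvement of ~0.15. The mix-in
replicates use all-phase features: under a pre-diagnosis restriction the
month-count feature `N` (cases stop contributing months at diagnosis,
controls never do) separates the classes almost perfectly and — being
availability, not level, information — transfers across regions undrifted,
so external AUC starts near 1 and leaves no room for the drift phenomenon.
With all-phase features every participant contributes the full observation
window and the model must rely on drifted activity levels.

## Numerical and design choices

* Day boundary: local midnight, half-open; record day = day of `start_time`.
* Lognormal truncation uses clamping at the physiological envelope; the
  probability mass involved is negligible (<0.2% everywhere).
* One top-level seed fans out to per-stage seeds by stable hashing
  (`derive_seed()`), so identical (config, seed) pairs give byte-identical
  cohorts and adding stages never perturbs upstream randomness.
* Problem sizes in the test suite (a 42-participant × 240-day record-level
  cohort shared across tests; 48-participant day-level cohorts for model
  tests) are the package's own choice of desk-scale study conditions with
  the same group proportions as the default roster.
* `BedBound` is computed but feeds no downstream stage by default.

## Known limitations

Monthly series are short (≤ 18 points at default spans), so spectral and AR
features are high-variance; the classifier can exploit availability
artefacts (pre-diagnosis cases have fewer months than controls — real
cohorts share this confound); the generator's independence of consecutive
days understates real autocorrelation, flattering the AR-feature null; and
synthetic calibration targets are medians/means, not full joint
distributions. None of the published real-data classification results are
claimed or reproduced by this package.
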