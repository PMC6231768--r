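---
title: "Methods: simulating, detecting and predicting COPD exacerbations from daily telemonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, detecting and predicting COPD exacerbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: what the
synthetic cohort generator emulates and why its parameters sit where they
do, how episodes, features, models and the validation scheme are defined,
the numerical choices that matter, and what passing tests do and do not
demonstrate about real telemonitoring data.

## 1. The generative model

Daily telemonitoring of severe COPD shows three regimes: long stable
stretches with background symptom noise, a prodromal build-up over a few
days, and frank exacerbations lasting one to two weeks. The simulator
(`cohort_config()`, `simulate_cohort()`) encodes this as a per-patient
first-order Markov chain over `stable`, `prodrome`, `exacerbation`, the
simplest latent structure that produces a prodromal signal which
threshold rules catch late and history-based models can catch early.
Transitions are parameterized by three daily probabilities (defaults
stable→prodrome 0.015, prodrome→exacerbation 0.20, exacerbation→stable
0.12), giving mean cycle lengths of roughly 67 stable days, 5 prodromal
days and 8 exacerbation days — a few exacerbations per patient-year, as
expected for a cohort enrolled with at least one admission in the prior
year.

Conditional on the state, the eight symptoms are independent Bernoulli
draws (`default_emission()`); the probabilities rise smoothly from stable
through prodrome to exacerbation (e.g. breathlessness 0.15 / 0.40 / 0.80).
Pulse and SpO2 are patient-specific baselines (pulse ~ N(80, 8) bpm,
SpO2 ~ N(93, 2) %) plus a state shift (up to +10 bpm, −4 %) plus daily
noise, clamped to physiological ranges ([30, 220] bpm, [50, 100] %).

Hospital admission is a daily Bernoulli draw from a logistic hazard
`plogis(-8.6 + 1.6*severity + 0.15*spo2_drop + 0.02*pulse_rise)` with
severity 0/1/2 and drops/rises measured against the patient's own
baseline and floored at zero. With 135 patients followed 363 days (the
cohort geometry of the telemonitoring service the package emulates) this
yields on the order of 40–60 admissions against ~49,000 patient-days —
prevalence of order 10^-3, the regime in which rare-event alerting
operates. Corticosteroid and antibiotic courses start from a logistic
hazard on the day's symptom count (defaults `-5.5 + 0.45*nAll` and
`-4.8 + 0.40*nAll`) and then run for 7 days; onsets (a start after a
non-use day) land at order 10^-2 per patient-day, i.e. several hundred
per cohort. An admission resets the latent state to stable; hospital
stays are not modelled and patients keep reporting, which keeps outcome
alignment simple.

**Missingness.** Patients mostly fail to submit a whole day rather than
single fields, so the model is day-level non-submission with probability
`plogis(qlogis(0.30) + u_i)` (patient effect `u_i ~ N(0, 0.7^2)`), plus a
small independent per-field dropout (0.02). On the 3 days before each
admission the daily rate is multiplied by 3 (capped at 1), emulating the
empirical observation that measurements stop arriving just before
admissions. Outcome flags and weather are never masked. With zero
dispersion and field rate, the marginal per-field missingness equals the
base rate exactly, which is how the calibration tests check it.

**Weather.** One shared daily series: a seasonal sinusoid (mean 9 °C,
amplitude 7 °C, coldest around day 17 of the year) with AR(1) noise so
cold snaps persist for days; 48-h mean/max temperatures, the three
standard cold indicators (mean < 2 °C, max < 4 °C, max < 7 °C) and an
ordinal population alert level are derived from it. By default weather is
independent of the patients, so weather-only classifiers sit at AUC ≈ 0.5
— deliberately, since individual-level weather prediction is the null
result the package should reproduce. Setting `couple_weather = TRUE` adds
`0.25 * max(0, 5 − mean_temp)` to every symptom-emission logit. The 0.25
value was calibrated once so that the weather-regression predictor of the
population symptom score attains Spearman correlations in the mid-0.6 to
mid-0.7 range on held-out blocks, the regime the coupled mode exists to
emulate, and was then frozen.

All randomness flows from one root seed through labelled child streams
(`child_seed(seed, "baseline")`, `"daily"`, `"missingness"`, ...), so
each module is reproducible in isolation and regenerating one table never
perturbs another.

**What the generator does not emulate:** self-management feedback
(patients medicating early and thereby averting admissions), spirometry
time series, hospital-stay gaps, device artefacts, and enrolment drift.
Passing tests therefore demonstrate internal correctness and the
qualitative mechanism (informative missingness degrading rule-based
detection; history features helping), not clinical performance on any
real service.

## 2. Rules, episodes, features

The five symptom-count definitions are implemented exactly as printed in
the clinical literature they come from (`detect_onsets()`); definitions
3–5 reference day *t*+1 and are flagged as impractical upper bounds.
Missing counts propagate three-valued logic: a day whose required context
is missing yields `NA` (an undetermined onset), while a known-false
conjunct still forces `FALSE`; series boundaries yield no onset. A day
with any missing symptom flag has undefined counts — there is no partial
counting, because the complete scenario only ever scores fully observed
days and the imputed scenario fills flags upstream.

`build_episodes()` materializes calendar gaps as all-missing rows
(windows need a contiguous day axis), then slides a `W`-day window. `W`
defaults to 7: the feature catalogue's longest lags and rolling windows
are 7 days, and longer windows would discard early follow-up. The
score-counting rules need no history, so the complete-data scenario
evaluates them on 1-day windows, while the imputed scenario shares the
7-day episode set with the models — making rules and models comparable on
identical episodes, at the price of the rules' imputed-scenario sample
being slightly smaller than their complete-data one per patient-day of
history required. Forward-fill carries the last observation at most 15
days and only ever backwards in time; indicator matrices record exactly
which entries were filled. Sparse patients (> 95 % missing maskable
fields, strictly) are dropped before anything else. For the
corticosteroid outcome, episodes whose day-*t* flag shows current use are
excluded, so a positive label is a treatment onset.

The 153-feature default catalogue (`default_catalogue()`) reconstructs a
plausible clinical time-series feature set: per-symptom current/lagged
values, 3- and 7-day counts, day-to-day deltas and recency; symptom-score
summaries including trend slopes and alert-day counts; per-vital rolling
means, extrema, SDs, slopes and threshold exceedances (SpO2 < 90 %, pulse
> 100 bpm); medication use and recency; imputation fractions per variable
and per group; and ten static baseline covariates imputed by population
median/mode. The telemonitoring variant with indicators and baseline
totals exactly 153 named features; the joint (+weather) variant trims a
documented subset to stay within the same budget, and the weather-only
variant has 21. The composition is auditable from the catalogue object
itself. Standardization is deliberately a model-side transform fitted on
training folds, keeping extraction fold-independent.

## 3. Models and validation

Three families behind one contract (`model_spec()`, `fit_model()`,
`tune_model()`): adaptive elastic-net logistic regression (glmnet, with
per-feature penalty factors set inversely to a univariate association
filter computed on the training fold — the package's reconstruction of
"adaptive" regularization with filter-informed priors), an RBF
max-margin classifier (kernlab), and boosted trees (xgboost). Class
imbalance is handled by inverse-prevalence instance weights, on by
default. Grid search for the first two, random search (seeded, budgeted)
for the boosted family; the inner-fold selection criterion is the AUC of
predictions merged across inner validation folds, consistent with the
outer aggregation.

Validation is patient-grouped nested cross-validation
(`make_folds()`, `run_nested_cv()`): patients (never episodes) are
assigned to outer folds by a greedy episode-count balancer; inner folds
are nested within the outer-training patients; an audit
(`audit_folds()`) verifies every split is patient-disjoint. Test-fold
scores are merged per run and the aggregated AUC is the mean of per-run
merged AUCs. Confidence intervals: DeLong (structural components),
patient-level cluster bootstrap (episodes within a patient are
dependent), and a Chebyshev bound using the DeLong variance; the
reported consensus is the conservative hull of the three, with each
member also reported so any other pooling can be recomputed. The CI is
computed on the pooled all-runs merged predictions; for deterministic
rule predictors the runs are identical, so one copy is used rather than
letting duplicates fake a larger sample. Ties in the AUC count one half
— required for 2-valued rule predictors to receive their natural
single-operating-point AUC. `fpr_at_tpr()` reports both the empirical
step value and the ROC-polyline interpolation, since a binary
predictor's step value overshoots the target sensitivity.

The population-level analysis (`population_score_prediction()`)
aggregates the baseline-adjusted symptom score (each patient's baseline =
median score over their first 28 observed days; the adjustment removes
stable between-patient burden) into 14-day blocks and compares a lagged
persistence heuristic with a linear regression on block-aggregated
weather covariates, fitted and evaluated with block-level
cross-validation, using Spearman and Kendall rank correlations.

## 4. Numerical choices and degenerate inputs

Deterministic seeds everywhere; ties in the fold balancer broken by a
seeded shuffle; `auc()` is the midrank Mann–Whitney statistic (exact
under ties); DeLong variance is undefined with fewer than two cases per
class and falls back, with a warning, to the bootstrap interval;
bootstrap replicates that lose a class are discarded; zero-variance
features receive unit scale during standardization; constant block
covariates are dropped before the population regression (they carry no
information and would make the fit rank-deficient); empty cohorts, empty
search spaces, single-class labels, and windows longer than any record
raise immediate, specific errors.

Test and acceptance problem sizes were chosen for statistical stability
rather than maximal fidelity: the default 135 × 363 cohort for the
headline comparisons; nested CV with 5 outer / 3 inner folds and 2
repetitions; rule complete-vs-imputed contrasts averaged over five
replicate cohorts and the oracle-dominance check pooled over ten,
because single-cohort AUC contrasts at ~10 admissions are dominated by
Monte-Carlo noise.

## 5. The oracle, and a limitation worth knowing

`oracle_scores()` returns the exact generative event probability, the
likelihood-ratio-optimal score *given the latent state and vitals*. When
missingness is non-informative this is an upper bound no fitted model
can systematically beat, and the package asserts exactly that on
replicate cohorts. With the pre-admission missingness multiplier active,
however, masking is drawn conditional on the *future* admission: the
imputation indicators then carry genuine predictive information that the
latent hazard does not contain, and models that read them can legitimately
out-rank the hazard propensity. This is not leakage in the software sense
— it is the data-generating process making missingness itself a symptom —
and it mirrors the clinical reality that a patient who stops reporting is
often a patient about to be admitted. It is also precisely the mechanism
that collapses count-based rules in the imputed scenario: their
stale forward-filled inputs blur the pre-admission signal, while the
models convert the same gaps into features. Users comparing their own
models against the oracle should do so under non-informative missingness.

Other known limitations: the feature catalogue is a reconstruction, not a
transcription of any service's exact feature list; the recurrent-network
family is out of scope; no post-admission blanking is modelled; and
cross-validated AUCs on simulated cohorts say nothing about transportability
to a real service without external validation.
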