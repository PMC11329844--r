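---
title: "Personalized next-week stress prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized next-week stress prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telestress)
```

## The problem

Psychological distress in office workers fluctuates week to week, and
passively collected data — wearable sleep/activity/heart-rate records and
attendance logs — carry signal about it. The difficulty is heterogeneity:
the same behavioral feature can relate to stress differently for an
employee who is in the office every day and for one who mostly works from
home. A single classifier pooled over a mixed workforce averages these
relationships away.

`telestress` implements a personalization strategy built on a single
scalar working-style descriptor, the **teleworking rate**: the fraction of
worked days spent working from home over the study period. For each
*prediction target* participant, training data are restricted to a
**neighborhood cluster** — the 20 participants with the nearest
teleworking rates — so that each per-target model learns from colleagues
with a similar working style.

## Data model

Three tabular streams per participant over a 12-week study:

* **Daily wearable records**: sleep duration, efficiency, start and end
  times; steps, distance, floors, calories; daily mean and SD of heart
  rate. Clock times are stored as signed minutes from midnight of the
  record's date (a sleep start of −30 is 23:30 the previous evening),
  which avoids midnight-wrap ambiguity.
* **Daily work-shift records**: actual and scheduled start/end times,
  scheduled hours, a work-from-home flag, an absence flag. Participants
  work Monday–Friday; wearable data cover all 7 days.
* **Weekly questionnaires**: the six K6 psychological-distress items
  (each 0–4), the number of outings, and the number of days lunch was
  skipped.

The K6 total (0–24) is binned into four classes — 0–4 (class 1,
stress-negative), 5–8, 9–12, ≥13 — and binarized as positive for class 2
and above. Weeks are Monday–Sunday, `week_index` 1 is the first study
week.

## Weekly features and the lag structure

Daily values are aggregated per week under fixed missingness rules: the
weekly mean is computed over whatever days are present and omitted only
when all 7 days are missing; the unbiased (n−1) SD requires at least two
present values. The default feature registry has exactly 50 entries:
weekly mean and SD of 15 daily variables (sleep, activity, heart rate, and
derived work variables such as working hours and the working-hour gap =
actual − scheduled hours), six weekly counts (worked days, WFH days,
absence days, within-week teleworking rate, outings, lunches skipped),
four weekly sums, five absolute deviations of weekly means from the
participant's study-long baseline, four week-over-week changes, and the
feature-week K6 total. The registry is a plain data frame and fully
replaceable; the prior-K6 entry can be dropped
(`default_feature_registry(include_prior_k6 = FALSE)`) by analysts who
consider questionnaire carry-over a leakage channel rather than a
predictor.

Supervised instances pair the features of week *t − 1* with the binary
label of week *t*, so a 12-week participant contributes at most 11
instances; week 1 has no predictor week and is never a label week.
Missing feature values are passed through to the learner, which handles
them natively via sparsity-aware splits — the modeling pipeline performs
no imputation.

## The three methods

All methods use the same gradient-boosted tree classifier
(`max_depth = 6`, `learning_rate = 0.3`, 100 rounds, binary logistic
objective, single-threaded and seeded; no hyperparameter search), and all
are evaluated on each target's final test weeks, pooled over targets
(micro average) into TP rate, FP rate, a confusion matrix and AUROC
(computed by the Mann–Whitney rank formulation with ties counted ½).

A convention is needed to split 11 lagged instances into "first 7 weeks"
of training and "latter 5 weeks" of testing: the split is by **label
calendar week** — training label weeks 2–7 (six instances, features from
weeks 1–6) and test label weeks 8–12 (five instances, features from weeks
7–11). This respects both period descriptions with no overlap.

* **single** — one pooled model: everyone's label weeks 2–7 train it,
  everyone's label weeks 8–12 test it; threshold fixed at 0.5.
* **proposed1** — per-target models: the cluster's full 11 instances plus
  the target's weeks 2–7 train; the target's weeks 8–12 test; threshold
  0.5.
* **proposed2** — per-target models trained on cluster + target weeks
  2–7; the cluster's weeks 8–12 are held out for **threshold
  adaptation**; the target's weeks 8–12 test.

A score greater than or equal to the threshold predicts positive — the
boundary must land somewhere, and this keeps the all-tied degenerate case
(every score identical) predicting positive.

### Threshold adaptation

The adapted threshold is chosen on the cluster's held-out weeks so the
true-positive rate exceeds 0.8 — catching stressed weeks early matters
more than false alarms — with the lowest attainable false-positive rate.
Candidate thresholds are the distinct observed scores plus one value above
the maximum; because TP and FP rates are step functions that only change
at observed scores, the FP-minimizing solution is always attained at a
candidate and the scan is exact. Remaining ties are broken toward the
highest threshold. Note the constraint is always satisfiable on the
adaptation data itself (a threshold at the minimum score yields TP = 1),
so `constraint_met = FALSE` can only arise through the defensive fallback
path, which is retained for non-standard targets; there is, however, no
guarantee the achieved TP rate transfers to the target's own test weeks.

### Neighborhood extraction

Cluster membership is by smallest absolute teleworking-rate difference.
When several candidates tie exactly at the boundary distance, the needed
number is sampled uniformly without replacement under a per-target seed,
making runs reproducible while honoring the tie. Rates are computed over
all 12 weeks for every method — the study design defines one rate per
participant — which implies a mild look-ahead for proposed2's rates (not
its labels); `telestress(..., rate_weeks = 1:7)` restricts rates to the
training period for analysts who prefer the stricter variant. The target
is never a member of its own cluster, and a target's test weeks never
enter its own training or adaptation sets (asserted structurally in the
test suite).

## Interpretation

Per-target models are explained in three steps:

1. **Gain importance** ranks features by the total objective reduction
   their splits achieve; ties (including never-used features, padded in at
   zero) break deterministically by feature name. The top 10 per model are
   tabulated.
2. **TreeSHAP** computes exact per-instance, per-feature contributions on
   the log-odds scale; row sums reproduce the model margin to numerical
   precision. SHAP is evaluated on each target's test instances — the
   weeks the deployed model actually predicts — rather than its training
   data.
3. The **direction statistic** cov(x, φ)/sd(x) (unbiased forms) condenses
   each feature's SHAP cloud into one signed value per model; it is
   undefined (reported as 0 with a flag) when the feature is constant over
   the evaluated weeks.

Models are then stratified by teleworking level — low (< 0.2), middle
(0.2 to < 0.6), high (≥ 0.6) — and each level reports top-10 occurrence
counts by feature category and features ordered by the mean of
within-model importance ranks. Mean-of-ranks is used because raw gain is
not comparable across independently fitted models; ranks are scale-free.
The three conventional reporting categories (sleep, activity, work) are
extended with a fourth, `questionnaire`, for features like lunches
skipped, rather than silently folding those into one of the three.

## The synthetic cohort generator

No participant-level data from the motivating study are distributable, so
the package ships a generator that emulates the three streams and plants a
known stress process, making every downstream stage testable against
ground truth.

* **Teleworking rates** default to a level mixture matching the observed
  workforce composition (43.2% low, 36.3% middle, 20.5% high), uniform
  within level and capped at 0.79 — full-time teleworking was not
  permitted in the emulated workforce. WFH days are allocated so each
  participant's empirical rate matches the assignment to within rounding.
* **Daily baselines** are participant-specific and plausible for desk
  workers: sleep around 420 minutes, steps lognormal around 8000, heart
  rate around 70 bpm, scheduled work 9:00–17:30 with 8 scheduled hours.
  Absences (3% of workdays), whole-day wearable gaps (5%) and skipped
  questionnaires (2%) exercise the missingness rules.
* **Labels** come from a logistic model on the *previous week's* features:
  standardized, optionally level-scoped planted effects, a participant
  random intercept (SD 0.5), and week-level noise (SD 1). The intercept is
  solved numerically so the marginal positive rate hits a configurable
  target, defaulting to 0.3 — high enough that per-target test weeks
  usually contain both classes at desk scale, and deliberately
  configurable because the emulated study never reports its own positive
  rate. U-shaped effects are implemented as the standardized squared
  deviation from the participant mean, matching "higher or lower than
  usual" contribution patterns.
* **Default planted effects** (±1.5 on the logit scale) differ by level
  and include opposite signs on the same feature (mean sleep duration:
  negative in low, positive in high; lunches skipped: positive in high
  only). Opposite-signed level-specific effects are exactly the regime in
  which neighborhood training should beat a pooled model, and the lunch
  effect mirrors the qualitative stratified finding the interpretation
  module is designed to surface.

What the generator does *not* emulate: per-minute heart-rate dynamics,
circadian structure, autocorrelated stress episodes, informative
missingness, or covariate shift between participants' device behaviors.
Passing tests therefore demonstrate that the pipeline recovers planted
structure under controlled conditions — not that comparable performance
would be achieved on real wearable data.

## Numerical choices and degenerate inputs

* The logistic intercept is found by `uniroot` on [−30, 30] at tolerance
  1e−10; the mean equation is monotone in the intercept so the root is
  unique.
* K6 totals are decomposed into six 0–4 items by uniform random
  allocation, preserving the total exactly.
* Single-class training sets raise a named error; the experiment driver
  skips such targets and records the reason instead of fitting a
  degenerate model.
* Adaptation sets without a positive label make the TP rate undefined;
  such targets are likewise skipped and logged.
* Participants with zero worked days have no teleworking rate and are
  excluded from clustering with a warning.

## Problem sizes

The test suite and the acceptance script exercise the pipeline on
60-participant, 12-week cohorts over 20 seeds — large enough that every
teleworking level is populated and each neighborhood draws from a real
pool, while keeping a full multi-seed three-method comparison comfortably
reproducible on a laptop. Unit fixtures use 3–25 participants.

## Known limitations

* Personalization rests entirely on the scalar teleworking rate; richer
  working-style descriptors (multivariate distances) are out of scope.
* SHAP directions quantify what the model uses, not causal effects of
  behavior on stress.
* The pooled (micro) evaluation weights participants by their number of
  test weeks; per-target macro averages can differ.
* Probability calibration is not attempted; the adapted threshold
  compensates operationally for the TP floor but transfers to test weeks
  without guarantee.
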