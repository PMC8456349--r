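---
title: "Predicting intradialytic adverse events: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intradialytic adverse events: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients on maintenance hemodialysis (HD) undergo roughly 4-hour sessions
in which fluid is removed by ultrafiltration while the dialysis machine
logs pressures and flows. A minority of sessions (about one in ten)
develops an intradialytic adverse event — muscle cramps, blood-pressure
excursions, hypotension, and two dozen rarer complaints — typically in the
second half of the session. `hdevents` implements a complete, testable
pipeline that predicts whether a session will develop an event from the
data recorded *before* it: irregular machine time series, sparse staff
vitals, and static patient fields.

Two properties of the data shape everything downstream:

* **Irregular, machine-triggered sampling.** The machine emits a record
  only when venous pressure (VP) or transmembranous pressure (TMP) changes
  beyond a threshold, so inter-record gaps are unequal and the value of any
  series at an arbitrary time is defined by last observation carried
  forward (LOCF). Staff vitals (systolic/diastolic blood pressure, pulse
  pressure, pulse rate) exist only at 30–60-minute visits.
* **Severe class imbalance.** With ~9.6% positive sessions, accuracy is
  meaningless; the pipeline reports ROC/AUC plus sensitivity, specificity
  and F1 at the model's native operating point, and the feature-selection
  score sums sensitivity and specificity so chance is ~1 of 2.

## Session cleaning

`clean_session()` applies three rules before any feature is computed:

1. **First-point artifact.** The first machine time point is dropped when
   the blood flow rate (BFR) differs between the first two recorded times
   — the pump is still being ramped up and the pressures are not yet
   informative. "Differs" is exact inequality: machine-reported values are
   integers in practice, so no tolerance is used. Staff vitals at time 0
   are not machine artifacts and are kept.
2. **Nonpositive-flow drop.** Every record whose contemporaneous BFR (by
   LOCF over the BFR series) is ≤ 0 is dropped; one maximal contiguous run
   of nonpositive-flow time counts as one interruption (urination breaks,
   dialyzer exchanges). Vitals timestamped inside the run are dropped too.
3. **Rejection rules.** A session interrupted more than once is rejected
   outright, as is a session left with fewer than 3 records for any
   measurement. The floor of 3 is the minimum for slope, R² and
   second-derivative features to exist; each exclusion carries an explicit
   reason in the clean report.

Cleaning is idempotent, which the test suite checks directly.

## The 84 features

`feature_registry()` fixes a canonical order for the 84 per-session
features:

| block | indices | content |
|---|---|---|
| static | 1–4 | gender (male = 1), age, dialysis vintage, predialytic weight |
| vitals & machine series | 5–46, 53–59 | per measurement: mean, SD of the mean, CV, OLS slope, R², max, min |
| VP derivatives | 47–52 | d² max/min/mean, d¹ max/min/mean |
| TMP derivatives | 60–65 | same six summaries |
| pulse-pressure d¹ | 66–68 | max/min/mean |
| change counts | 69, 84 | VP and TMP record-change counts |
| ultrafiltration rate | 70–77 | five summaries, max, change count (76), mean change (77) |
| ultrafiltration volume | 78–83 | max (78), mean, SD of mean, CV, slope (82), R² |

Group tags drive the ablation experiments: `uf_rate` (8) + `uf_volume`
(6) form the 14 ultrafiltration features, whose complement has 70 columns;
`bp_related` has exactly 24 columns (the three blood-pressure blocks plus
the pulse-pressure derivatives); `top21` marks the 21 key features most
frequently retained by the greedy search on the reference cohort, none of
them ultrafiltration-tagged. Where the published account of the top
features names one more summary than its own count of 21, the registry
resolves the overflow by leaving mean venous pressure out of the group;
the per-index layout beyond the pinned anchors is this package's own
canonical ordering, not a claim about the original analysis table.

Numerical conventions, chosen once and tested against brute-force
definitions to 1e-10 relative:

* *SD of the mean* is the standard error, sample SD/√n (the plain sample
  SD is also exposed). *CV* is sample SD/|mean|, 0 for a constant series;
  a zero mean with positive SD is flagged non-finite and excludes the
  session for that feature (pressures and flows are positive in practice).
* *Slope/R²* are unweighted OLS of value on time at the recorded points
  only — densifying to a regular grid by LOCF would distort every variance
  feature. A constant series has slope 0 and R² defined as 0. Slopes and
  derivatives are per minute.
* *Derivatives* are finite differences over consecutive records; the
  second difference divides by the later interval. Duplicate timestamps
  collapse to the last value before differencing.
* An *ultrafiltration-rate change* is any consecutive pair of records with
  different values; the mean change is the mean of the signed differences
  over changed pairs (0 when there are none).

## Outcome labels and truncation

A session is labeled 1 under a scheme when it has at least one in-scope
event: `any_event`, `group1` (everything except blood-pressure elevation
and vascular-access occlusion/thrombosis), `group2_cramps`, or
`group3_bp_elevation`. For positive sessions only data *strictly
preceding* the first in-scope event enter feature extraction; a session
whose only events are out of scope is a label-0 session and keeps its full
record, since its event did not define the analysis endpoint.

The cutoff experiment generalizes this: feature collection terminates at
0, 5, 10, 15, 20 or 60 minutes before the first event (or before the last
record of an event-free session). Cutoff 0 means "one time point before
the event" (open right endpoint); positive cutoffs include the endpoint
`anchor − m` itself. The leakage guard in the test suite mutates every
record after the cutoff anchor and requires bit-identical features and
scores.

Because positive sessions are truncated (mean event time well before the
scheduled end), session *length* itself is a potential confound. The
truncation experiment therefore cuts event-free sessions to matched
endpoints — fixed 198 min (3.3 h), or per-session uniform draws from
180–210 min or 150–210 min — appending an LOCF record at the endpoint for
every measurement, exactly how the data set is defined at an arbitrary
termination time.

## Models

The primary classifier is a **two-class averaged perceptron** written in
this package: per epoch, examples are visited in a seed-shuffled order; a
misclassification under the ±1 convention triggers `w ← w + lr·y·x`; the
model returned is the average of the weight vector over *all* visits,
which is far more stable than the final iterate. Defaults are learning
rate 20 and 20 epochs. Features are standardized (SD floor 1e-8) with
parameters fit on training folds only — a learning rate of 20 is only
meaningful on a bounded scale, and the floor silences zero-variance
columns. Ties at the decision threshold classify as 0, favoring
specificity, which matches the high-specificity/low-sensitivity operating
point expected under ~10:1 imbalance. The "probability of an adverse
event" is the logistic squashing 1/(1+e^(−score)); the consistency
experiment applies its 0.8 threshold to this value (floored at the
smallest positive double, since extreme negative scores underflow).

The feature-selection scorer is **RUSBoost**: AdaBoost.M1 in which each
round first undersamples the majority class uniformly at random to a 1:1
ratio against the minority, fits a weighted `rpart` tree (depth 1–4,
default 2), computes the round weight from the weighted error on the full
set, and reweights. Baseline adapters (linear SVM via `e1071`, logistic
regression via `glm`, decision forest via `randomForest`) expose the same
train/score contract and serve as cross-checks, never as the primary
implementation.

## Evaluation

AUC is the Mann–Whitney probability that a random positive outscores a
random negative, ties counted ½, computed from rank sums and verified
exactly against the pairwise estimator. Cross-validation is 4-fold with at
least 3 seeded repeats; folds are label-stratified under the session
partition, or assign whole patients to folds under the interpatient
partition. All preprocessing that learns from data (standardization,
undersampling) happens inside the training folds. Mean ROC curves average
TPR vertically on a fixed FPR grid. A held-out fold with one class skips
AUC with a warning rather than fabricating a value.

The **negative control** permutes the labels across sessions at exactly
preserved 0:1 counts (a permutation, not a fresh Bernoulli draw — that is
the reading of "same ratio" that conserves the count for every seed). A
calibrated pipeline must score mean AUC ≈ 0.5 on the permuted labels; the
acceptance script recomputes this end to end on a ~4200-session synthetic
cohort and lands within ±0.05 of 0.5 across seeds.

## Greedy feature-combination selection

`greedy_forward_search()` scores every single feature (4-fold RUSBoost CV,
score = sensitivity + specificity), keeps the top one, then repeatedly
extends every retained combination by each unused feature, keeping
extensions that *strictly* beat the best retained score of the previous
level, up to 20 features. The scoring seed — and hence the folds — is
fixed within a level so comparisons are paired. Two deliberate deviations
from a literal keep-everything rule, both configurable:

* a per-level **beam cap** (default 50, `Inf` for small problems) bounds
  the combinatorial growth of the retained lists, truncating by score with
  deterministic tie-breaks (then lexicographic combination order);
* the level benchmark is the best retained score of the previous level,
  applied per level rather than per parent.

On problems of ≤ 8 features the uncapped search is verified identical to
exhaustive level-by-level enumeration under the same keep-if-better rule.
The search is greedy by construction, not globally optimal: a feature pair
informative only jointly is found only if one member survives level 1.
`key_features()` ranks features by how often they appear in the deepest
retained combinations (ties: best containing-combo score, then lower
index). The alternative reading of the selection score — true positives
and true negatives as fractions of all examples, range 0–1 — is available
behind the `convention = "counts"` switch.

## The synthetic cohort generator

No public HD cohort with per-record timestamps and event annotations
exists, so `simulate_cohort()` generates one with the statistical
structure the analysis assumes and a *known* event mechanism:

* **Latent trajectories.** Each pressure channel follows patient baseline
  + session-level linear drift + discretized Ornstein–Uhlenbeck jitter
  (mean-reversion time 30 min, stationary SD 6 mmHg) on a 2-minute grid.
  This is the minimal structure giving nontrivial slopes, variances and
  derivatives; no cardiovascular or plasma-refill model is claimed.
* **Trigger discretization.** A machine record is emitted when VP or TMP
  has moved more than `machine_trigger_sd` (default 5 mmHg) since the last
  emitted record, plus forced records at session start/end and at
  ultrafiltration-rate adjustments — so gaps are irregular by
  construction. Vitals appear at staff visits spaced U(30, 60) min.
  Ultrafiltration rate is piecewise constant (staff adjust it a
  Poisson(1.2) number of times); cumulative volume is its exact integral,
  hence nondecreasing.
* **Event mechanism.** The per-session hazard is logistic in z-scored
  session-level latent quantities named in `signal_features`
  (default: negative effect of the systolic drift slope, positive effect
  of the mean ultrafiltration rate), with the intercept calibrated by
  root-finding so the mean probability equals the configured event
  fraction (default 0.096). Event times fall in the second half with
  probability 0.8 (rising-density triangular there); multiplicities follow
  the observed 276:106:19:4 split of 1/2/3/4-event sessions; types follow
  the observed episode distribution. With an empty signal list, labels are
  independent of features — the null the negative control must recover.
* **Demographics.** Age ~ Normal(64, 12) truncated above 18 years (mean
  ≈ 63.6), 56% male, vintage ~ Gamma with mean 7.7 years, weight ~
  Normal(62, 11) kg truncated above 35; 108 patients × 39–40 sessions by
  default (~4200 sessions).

All randomness flows from one root seed through named substreams
(statics, trajectories, events, interruptions), so each stage is
independently reproducible and a config is bit-reproducible end to end.
`simulate_interruptions()` injects zero-flow runs (avoiding the first two
and last flow records, with double runs separated by clean records) and
records the injected counts, so the cleaner's decisions can be required to
agree *exactly*.

**What passing tests do and do not show.** The generator reproduces the
sampling structure, imbalance, event timing and a controllable
feature–hazard coupling; it does not reproduce physiological waveforms,
comorbidity structure, staff charting behavior, or the real cohort's
feature correlations. Recovery of an injected signal and a chance-level
negative control demonstrate that the pipeline is correct and leak-free —
not that any particular AUC is attainable on real dialysis data.

## Problem sizes used by the shipped checks

Chosen as this package's own trade-off between statistical resolution and
a test suite that runs in minutes: the negative-control calibration runs
at full study scale (~4200 sessions, 4-fold × 3 repeats); signal-recovery
uses a 15-patient cohort (~580 sessions) with a single strong
ultrafiltration signal (effect 2.5 log-odds/SD), scored by stump-tree
RUSBoost with beam 3 to combination size 3; oracle suites use 1000 random
instances each; the cleaning agreement check uses 500 sessions. The
selection oracle uses 8 features to keep exhaustive enumeration exact.

## Known limitations

* Index-level fidelity of the 84-feature table to any external analysis is
  not claimed; only the documented anchors and group sizes are pinned.
* The averaged-perceptron learning-rate semantics of commercial AutoML
  platforms are undocumented; equivalence to any such implementation is
  not claimed, only to the standard averaged-perceptron algorithm.
* The hazard model is per-session, not a point process in time; event
  *times* carry no information beyond the second-half bias, so
  time-to-event methods are out of scope.
* LOCF is the only imputation; there is no smoothing, outlier handling, or
  frequency-domain feature set.
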