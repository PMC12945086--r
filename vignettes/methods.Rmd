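---
title: "Methods: Thompson-sampling behavior recommendation and longitudinal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Thompson-sampling behavior recommendation and longitudinal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emibandit)
```

`emibandit` implements the computational core of a mobile ecological
momentary intervention for obesity: a per-user multi-armed bandit that
orders a catalog of daily weight-loss behaviors by how achievable they are
for that person, the event data model for the daily set/review cycle, a
synthetic cohort generator, and the longitudinal statistics used to study
feasibility and the daily predictors of behavior. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions that were genuinely open.

## 1. The bandit engine

### Model

Each behavior is an independent beta-Bernoulli arm. With `N` reviewed
selections and `a` completions, the completion probability has density
proportional to `theta^a * (1 - theta)^(N - a)`, i.e. Beta(a + 1, N - a + 1):
a uniform Beta(1, 1) prior updated by `a` successes and `N - a` failures.
Ranking draws one score per arm from its posterior and sorts descending
(Thompson sampling). No hyperparameters need tuning; arms with little data
retain wide posteriors and are explored, arms with high completion rates
are exploited. Each participant's model uses only that participant's
reviews — with 20-ish users there is no pooling to be had, and independence
keeps the per-user model auditable.

### Assumptions

* Completions are Bernoulli with a stationary per-behavior probability.
  Real achievability drifts (weather, motivation, the study itself); the
  posterior mean converges to the long-run average.
* Arms are independent: completing one behavior neither helps nor hinders
  another on the same day. This is clearly an approximation (time budget,
  fatigue) and is the standard one for this design.
* Reward is completion, not clinical benefit: the engine optimizes for
  *doing* behaviors, deliberately agnostic to how much each contributes to
  weight loss.

### Decisions that were open

* **Counter timing.** Selections are counted only when the matching review
  arrives. Counting at selection time would treat every unreviewed day as
  an implicit failure and bias arms toward incompletion whenever a user
  skips an evening; review-time counting keeps `N` and `a` synchronized.
* **Ad-hoc extras.** A behavior logged at review without having been
  selected does *not* update its arm by default, because the selection
  counter is defined as "times the user chose the item". `apply_review(...,
  include_extras = TRUE)` enables the other reading (extras count as
  selected-and-completed); both are supported because a deployed system
  could justify either.
* **Tie-breaking.** Sampled-score ties have probability zero in theory but
  must be deterministic in practice for bit-exact replay: ties break by
  lexicographic `arm_id`.
* **Ranking cadence.** Every ranking call draws fresh scores; nothing is
  cached across evenings. The full catalog is always ranked — truncating
  the display is a presentation concern left to callers.
* **Reproducibility.** Each user's stream is (seed, draw counter): every
  ranking call derives a per-call seed from the pair, so a serialized state
  (JSON: counters, seed, draw count) replays its future rankings exactly,
  and library calls never consume the caller's RNG.

## 2. The event-log data model

Events are JSON Lines with a header (per-user metadata, timezone, bandit
seed) followed by `set`, `review`, `mood`, and `weight` events with
ISO-8601 timestamps. The choices that matter downstream:

* **Pairing rule.** A review is matched to the most recent prior set event
  of the same user with a gap strictly inside (12, 36) hours; pairing is
  one-to-one, the earlier review claims a contested set, and unmatched
  events are counted in a drop report rather than silently discarded. The
  strict inequalities matter at the boundary: a review exactly 12 h after
  setting is excluded.
* **Daily outcome.** `Y` = number of preselected behaviors performed +
  number of extras. It is invariant to the ordering of entries.
* **Mood scoring.** Nine 0–100 visual-analog items map to three subscales
  (depression, anxiety, positive affect), each the mean of its three items
  divided by 100. The item-to-subscale assignment is configuration
  (default: items 1–3 depression, 4–6 anxiety, 7–9 positive affect)
  because instrument versions order items differently; positive affect is
  its own subscale and is never reverse-scored into depression.
* **Use rate.** 100 × distinct calendar review days / scheduled days,
  reported to one decimal. The denominator defaults to 28 but is per-user
  configurable: a participant scheduled for 26 days with 20 recorded days
  has a use rate of 76.9%, which is not expressible as an integer fraction
  of 28 — real cohorts do have per-user denominators.
* **Weight covariates.** At review time, the latest weight strictly before
  the review yields the delta from the user's first observation and from
  the previous observation. Records lacking the previous-weight covariate
  are excluded from models that use it (complete-case); no imputation.
* **Calendar days** use the participant's timezone from the log header
  (default UTC).

## 3. The cohort simulator

Two generators serve different purposes.

### Mechanistic simulator (`simulate_cohort`)

Emulates the full app loop so the entire pipeline — bandit, log I/O,
pairing, ETL, feasibility — can be exercised end to end. Defaults define
the emulated study conditions: 20 participants, 28 days, a 20-item catalog.
Per participant:

* latent completion probabilities `p_k ~ Beta(2, 2)` (mean 0.5, broad) —
  no empirical distribution of achievability exists, so this free choice
  is deliberately prominent here and in `sim_params()`;
* mood subscales follow a clamped AR(1) on [0, 1] (depression and anxiety:
  mean 0.30, autocorrelation 0.6, innovation SD 0.08; positive affect:
  mean 0.55, 0.6, 0.10) — the minimal temporally-correlated process, since
  nothing richer is identified by the data the study design collects; the
  nine visual-analog items are the subscale value times 100 plus small
  item noise;
* completion of behavior k on day t is Bernoulli with
  `logit(p) = logit(p_k) + depression_effect * depression_t`,
  `depression_effect = -1.5` by default — a logit link keeps probabilities
  valid while encoding the worse-mood/fewer-behaviors mechanism;
* the simulated user selects the displayed item at rank r with probability
  `0.9 * 0.7^(r-1)` (at least one item always selected): geometric
  attention decay, ~3 selections per evening, which over four weeks
  yields a median of roughly a dozen distinct behaviors performed;
* reviews are skipped independently with probability 0.05, calibrated so
  simulated use rates land in the mid-90s (the feasibility range reported
  for this class of intervention); skipped selections never update the
  bandit;
* weight is baseline (normal, mean 95 kg, SD 15, truncated at 60) plus a
  drift of −0.08 kg/day and 0.3 kg noise — linear drift is enough for the
  covariate pipeline, clinical realism is out of scope;
* 30% psychiatric comorbidity, 55% female, baseline BMI normal
  (mean 35, SD 5, truncated at 27).

What the simulator does *not* emulate: item content, notification timing,
questionnaire internals (diet and physical-activity scores enter analyses
as exogenous numbers), GLP-1/bariatric subgroups as distinct mechanisms,
and any drift or feedback in achievability. Tests passing on simulated
cohorts therefore validate the *pipeline and estimators*, not claims about
real participants.

### Direct two-level generator (`generate_lmm_dataset`)

Draws the outcome exactly from the model the statistics module fits:

* `Y_ij = (gamma00 + zeta0_i) + (gamma10 + gamma11 * Psych_i + zeta1_i) * Depression_ij + eps_ij`

with defaults `gamma00 = 4.45`, `gamma10 = -1.88`, `gamma11 = 1.59` (the
study-scale coefficient values), `zeta0 ~ N(0, 2.0^2)`,
`zeta1 ~ N(0, 1.0^2)` (independent in the generator; the fitted model
estimates their correlation), `eps ~ N(0, 2.2^2)`, 20 participants × 22
observations (~440 records, the scale of the study's 432), depression
`~ Beta(2, 5)` (mean ≈ 0.29, matching mood scored on [0, 1]), psychiatric
comorbidity Bernoulli(0.3). The variance components were chosen once so
that the Wald standard errors of the fixed effects at this sample size
resemble the reported interval half-widths (≈0.5 for the intercept and
slope). Null covariates (anxiety, positive affect, weight deltas, week,
sex, centered BMI) are included for model-selection experiments.

Keeping this generator separate from the mechanistic one makes parameter
recovery a clean check of the estimator against its own generating
process, while the mechanistic simulator stress-tests everything upstream.

### Episode harness

`run_bandit_episode()` plays one arm per round (the top-ranked), reviews
it, and records instantaneous regret `max(p) - p(selected)`.
`suggestion_diversity()` counts distinct arms in the top-3 positions over
a window of rounds; comparing the first week against the last
operationalizes the "monotony" users report as the sampler converges. With
three arms the top-3 trivially contains everything, and even five arms
saturate a 7-round window, so diversity experiments here use a 10-arm
catalog with probabilities 0.9, 0.8, ..., 0.0 (measured at 500 replicates:
median 9 distinct arms in the first week vs 6 in the last).

## 4. The statistics pipeline

### Wilcoxon signed rank

Two-sided, on paired differences; zeros dropped and the effective n
reported; all-zero differences give a degenerate flagged result with
p = 1 rather than an error. The exact path computes the null distribution
of the positive-rank sum by convolution over the tie-averaged ranks
(doubled to stay integral), which equals full `2^n` sign enumeration, and
is used when requested or automatically for n ≤ 25 without ties; otherwise
the normal approximation applies continuity and tie corrections. No
multiple-testing adjustment is applied across pre/post measures, matching
single-threshold reporting at 0.05.

### Two-level mixed model

`fit_lmm()` builds the model from an `lmm_spec()`: level-1 fixed effects
(mood subscales, weight deltas, week), level-2 fixed effects (sex, BMI
centered by subtracting 35, psychiatric comorbidity), cross-level
interactions, and random effects (person intercept, optionally a person
depression slope, correlation estimated). Estimation is **maximum
likelihood, not REML**, so AIC comparisons across fixed-effect structures
are valid. CIs and p-values for fixed effects are Wald; at 20 groups their
coverage runs a little below nominal (measured ≈0.91–0.95 in the recovery
harness), which is the standard small-sample behavior of Wald intervals in
mixed models.

One admissibility rule deserves a note: a cross-level interaction requires
its level-1 main effect but **not** the level-2 main effect. This mirrors
the multilevel formulation — the interaction *is* the level-2 variable
entering the slope equation, and a model can legitimately moderate the
slope without shifting the intercept (the canonical final model here does
exactly that: depression × psychiatric comorbidity with no comorbidity
main effect).

Degenerate inputs are first-class: a rank-deficient fixed-effect design is
an error naming the collinear columns; single-group data or other
fit failures are flagged as non-converged, never silent. One numerical
special case: in the perfect-fit limit (residual variance ≈ 0) the
optimizer's gradient checks produce spurious convergence warnings even
though the estimates are exact, so a fit with residual SD below 1e-8 is
treated as converged.

### Model selection

`select_model_aic()` searches exhaustively — all subsets of the level-1
and level-2 candidates, all admissible interaction subsets, each
random-effect option — rather than stepwise, which is affordable at this
candidate-set size (tens to a few hundred models) and removes path
dependence. Only converged models compete; ties break by fewer parameters,
then lexicographically, so selection is deterministic. Candidates whose
design is degenerate on the given data are recorded as non-converged
rather than aborting the search.

### Parameter recovery

`recover_parameters()` regenerates datasets from the two-level equations,
refits, and reports per-coefficient bias, RMSE, and 95% CI coverage,
excluding (and counting) non-converged replicates — including replicates
whose drawn design is degenerate, e.g. a cohort with no comorbid
participants, which happens with probability `0.7^20 ≈ 0.08%` per
replicate at the defaults. At the default 200 replicates of 20 × 22
observations, mean estimates land within a few percent of the generating
values and coverage within [0.90, 0.98] for all three coefficients.

## 5. Problem sizes and numerical choices

* Posterior-vs-quadrature checks run the full counter grid N ≤ 50 with
  composite Simpson integration (8001-point grid; worst-case disagreement
  with the closed form is ~1e-12, far inside the 1e-8 tolerance asserted).
* Distributional checks use 1e5 draws (KS distance ≲ 0.003 against the
  quadrature CDF).
* Bandit convergence/regret and diversity experiments use 500 replicates
  of 200 review rounds; recovery uses 200 replicates. These sizes give
  Monte-Carlo error comfortably below the margins being asserted while
  keeping a full run in minutes on one core.
* All simulation entry points take a single seed; per-replicate and
  per-user streams are derived deterministically from it, so every
  reported number replays exactly.

## 6. Known limitations

* Stationary, independent arms; no contextual features, no collaborative
  filtering across users, no reward shaping by clinical outcome.
* The simulator's mood process and attention law are modeling choices, not
  estimates from data; conclusions about real cohorts require real logs.
* Wald CIs slightly undercover at 20 groups (see above); profile or
  bootstrap intervals would be the upgrade path if coverage mattered at
  the third decimal.
* The feasibility metrics treat a day as reviewed if any review event
  falls on it; partial reviews are not modeled.
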