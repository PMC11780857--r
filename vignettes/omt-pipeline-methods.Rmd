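---
title: "Models and methods behind the omtkit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the omtkit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and its measurement model

The "What was where?" Oxford Memory Task (OMT) is a delayed-reproduction
visuospatial short-term memory test used to stratify people along the
Alzheimer's disease continuum: elderly healthy controls (EHC), subjective
cognitive decline (SCD), mild cognitive impairment (MCI) and Alzheimer's
disease dementia (AD). On each trial 1 or 3 fractal stimuli appear at
pseudorandom screen locations; after a 1 s or 4 s delay the participant must
identify which of two probe items was in the array and drag it back to its
original location. A session comprises 8 practice trials and three test
blocks of 40 trials, 10 per (set size × delay) condition per block — 120
test trials.

Because the response is a point in a continuous 2-D space, localization
errors can be decomposed. The working-memory resource account treats each
response as coming from one of three sources: the **target** location (with
Gaussian imprecision), the location of **another item** of the same array
(misbinding, also called swap errors), or a spatially unrelated **guess**.
`omtkit` implements both the generative side (a simulator producing trial
data from known mixture parameters) and the estimation side (the
permutation-based decomposition, plus the surrounding group-comparison,
longitudinal, regression and classification analyses), so that every stage
of the analysis can be validated by parameter recovery on synthetic data.

# Session schedules

`make_session_schedule()` reproduces the design constants exactly: a
196-item stimulus library (49 shapes × 4 colours), exact condition balance
within each block with per-block random trial order, and a foil drawn from
the library excluding the trial's own items. Locations live in the
normalized screen square $[0,1]^2$ (origin top-left); physical stimulus
size is not modelled. Two constants are not fixed by the task description
and were chosen once for geometric plausibility: a minimum pairwise item
separation of 0.15 screen fractions and an edge margin of 0.10, enforced by
rejection sampling with a 10,000-attempt budget. Stimulus reuse across
trials is allowed (196 stimuli cannot cover 280 item slots), never within a
trial.

# The generative response model

`sample_response()`/`simulate_trial_responses()` draw, per trial:

* identification success $\sim$ Bernoulli$(p_{\mathrm{id}}(c))$ with a
  separate probability per condition $c$;
* given success, a component $\sim$
  Categorical$(p_t, p_m, p_g)$, $p_t+p_m+p_g=1$. On 1-item trials
  misbinding is undefined (it needs a second object), and its mass is
  reallocated proportionally to the other two components;
* target responses: target location plus isotropic Gaussian noise with SD
  $\sigma$ (screen fractions), truncated to the screen by resampling;
  misbinding responses: the same noise around a uniformly chosen non-probed
  item; guesses: uniform over the placement region;
* identification and localization times from lognormal distributions. The
  underlying study reports no distributional detail for response times;
  lognormal is this package's choice and nothing downstream depends on it
  beyond a positive skewed time.

Failed identifications receive a uniform response location and component
label `"none"`; all estimators discard these trials.

Gaussian (not von Mises) noise is used because the response space is a
plane, not a circle; truncation bias is negligible at realistic $\sigma$
(checked in the tests: mean signed displacement under 0.005 screen
fractions for central targets at $\sigma = 0.05$).

# Clinical-group presets and the latent severity model

`default_group_presets()` orders the four groups by severity: target
detection and identification accuracy fall, misbinding, guessing,
imprecision and response times rise from EHC through SCD and MCI to AD
(EHC mixture 0.80/0.08/0.12 with $\sigma = 0.040$ through AD
0.55/0.18/0.27 with $\sigma = 0.070$). These are simulator settings that
realize the qualitative group ordering of the clinical literature, not
estimates of any real cohort.

`make_cohort()` individualizes the presets through two latent variables:

* a **severity** $s$ (group-specific mean, SD 0.55) that also generates the
  ACE screening score (baseline 97, −10 points per severity unit, SD 2.5,
  clipped to 0–100) and hippocampal volume (baseline 8300 mm³, −900 mm³
  per unit, SD 350 mm³). Because the same $s$ moves the task parameters,
  ACE and HV, task metrics are correlated with both — which is what the
  HV-regression and decline-prediction analyses exploit;
* a **general-competence trait** (SD 1.0 severity units) that shifts all of
  a participant's parameters jointly but is independent of diagnosis. This
  term is essential for realism: eight precisely measured metrics with only
  independent per-metric noise would separate the groups almost perfectly,
  whereas real cohorts of this kind classify with pairwise AUCs well below
  1. The trait caps multi-metric separability at roughly the reported
  scale (EHC-vs-AD near 0.98, MCI-vs-AD around 0.99 here; real data are
  harder still).

Loadings are applied on the logistic scale for probabilities and the log
scale for $\sigma$, with small independent per-parameter jitter (logit SD
0.30, log-$\sigma$ SD 0.15). Demographics differ by group (SCD youngest, AD
least educated) so that covariate adjustment is genuinely exercised.

For two-session (longitudinal) cohorts, severity progresses by
$0.25 + 0.5\,s$ per year (faster at higher baseline severity), which makes
baseline task performance predictive of the one-year ACE change; the
progression slope and ACE noise were set so the strength of that designed
coupling (baseline imprecision vs ACE change, $R^2 \approx 0.3$–0.4) is of
the order reported for this paradigm. The AD preset additionally drifts at
the second visit ($p_t$ −0.07, $\sigma$ +0.03, $p_{\mathrm{id}}$ −0.06),
calibrated so the within-AD paired session effect on localization error has
standardized magnitude $|d| \approx 1.3$, matching the reported size of
that longitudinal effect; the other groups are stable.

# The permutation mixture decomposition

For every correctly identified trial, `attribute_trial()` repeats the
following 5000 times (the reference repetition count): draw one item
location uniformly, with replacement, from the pool of all item locations
of the participant's other test trials, then classify the response to
whichever is closest — the target, the nearest non-probed in-trial item, or
the drawn location. The per-trial proportions (counts / 5000) estimate
target detection, misbinding and guessing: a response that even a random
other-trial location frequently beats is a guess, one tied to an in-trial
item is a swap.

Numerical conventions, fixed for determinism:

* ties (probability zero for continuous data) resolve target ≻ in-trial
  distractor ≻ random draw;
* with two non-probed items the *minimum* distractor distance is used —
  misbinding is a swap to *any* other array item;
* 1-item trials have no in-trial distractor: misbinding is exactly 0 and
  the classification is two-way;
* the pool excludes the current trial and the practice block.

`exact_attribution()` enumerates each pool element once. Since the pool
draw is the only randomness, this is the analytic expectation of the
permutation estimator — it serves as the test oracle and as a faster
deterministic drop-in (`method = "exact"`).

Per-participant metrics (`participant_mixture()`) average trial
attributions within each condition and then across conditions with equal
weight, the task's standard cumulative measure; misbinding averages over
the two 3-item conditions only. **Imprecision** is the SD of the radial
response–target distance weighted by each trial's target-attribution
proportion, aggregated the same way. The "width of responses around the
target" is not otherwise formalized; the weighting approximates "responses
attributed to the target" without a hard assignment.

Two estimator properties are deliberate and documented rather than hidden:
nearest-location attribution misclassifies overlapping components (e.g.
guesses that land near the target), so estimates are biased toward the
dominant component; and the target-weighted imprecision compresses large
$\sigma$ (far responses get little target weight). The test suite therefore
asserts *monotonicity* in the generative parameters — the property the
group comparisons actually rely on — not unbiasedness.

# Inferential machinery

* **Cross-sectional group comparison**: linear model
  `metric ~ group + age + gender + education`, Type II omnibus F with
  partial η² (what standard ANCOVA software reports), pairwise
  covariate-adjusted contrasts via estimated marginal means with Holm
  correction (`stats::p.adjust`). Cohen's d is computed on raw,
  unadjusted group values with a pooled SD — the adjustment convention is
  not specified by the reference analyses, so the simpler raw-scale d is
  used and stated.
* **Set-size × delay**: repeated-measures two-way ANOVA (`stats::aov` with
  participant error strata) on per-condition values; classical η²
  (effect SS / total SS) classed >0.14 large, >0.06 medium, >0.01 small.
  Misbinding, undefined at set size 1, gets the delay-only one-way variant.
* **Longitudinal**: mixed ANOVA with group between, session within,
  covariates entered before group; post hoc per-group paired session
  t-tests, Holm-corrected within the metric.
* **Decline prediction**: ACE change (follow-up − baseline) regressed on
  each baseline metric separately.
* **Dependent overlapping correlations**: the Hittner–May–Silver
  modification of Dunn & Clark's z (backtransformed-average Fisher z in
  the covariance term) as default, Steiger's variant selectable —
  $z = (z_{jk} - z_{jh})\sqrt{(n-3)/(2-2c)}$.
* **Classification**: linear SVM (`e1071`), stratified 5-fold
  cross-validation, features standardized with training-fold statistics
  only, balanced class weights, C = 1 (the reference analysis does not
  state its scheme; these defaults are fixed and exposed). Per-class ROC
  from one-vs-rest decision values on held-out folds; model comparisons
  use the paired DeLong test on out-of-fold scores, implemented from
  placement values so both models are compared on identical cases.

# Calibration and validation strategy

The package ships an acceptance suite (`tests/testthat/test-acceptance.R`,
re-runnable via `scripts/acceptance.R`) that validates, at desk-scale
problem sizes chosen to keep the full suite in the tens of minutes:

1. design constants (120/8 trials, 196 stimuli);
2. the permutation estimator against the exact enumeration oracle (200
   random geometries, 3-binomial-SE agreement at 5000 repetitions);
3. exact normalization and the set-size-1 misbinding zero;
4. parameter recovery: monotonicity of all four mixture estimates across
   3-point generative grids, 20 replicate seeds, 6–10 simulated
   participants (120 trials each) per grid point;
5. type-I calibration of the ANCOVA omnibus, Holm familywise contrasts,
   h-test and paired DeLong test on null simulations (600–2000 replicates;
   all must fall in [0.035, 0.065] at α = 0.05);
6. planted-effect detection: the AD-only session drift must produce a
   Group × Session interaction with AD-only post hoc significance in ≥80%
   of 20 seeds; severity-linked cohorts must show positive
   identification-accuracy→HV association and imprecision→decline
   prediction;
7. classifier sanity: chance AUC under label permutation; EHC-vs-AD AUC
   strictly above MCI-vs-AD in ≥90% of 20 seeds.

# What passing tests do and do not show

The simulator emulates the design, the mixture structure, group ordering,
covariate confounding, severity-linked ACE/HV and two-session drift. It
does **not** emulate: learning and fatigue within a session, spatial
response biases (edge repulsion, centre bias), tablet motor noise,
diagnosis conversion, missing data, or the heavier tails of real clinical
populations. Passing recovery and calibration tests therefore show the
pipeline is *internally correct* — it recovers what the generative model
planted and its tests hold their error rates — not that the published
clinical effect sizes would replicate on new data. The real-cohort values
(group F statistics, AUCs, decline R²) depend on a non-public patient
sample and are intentionally out of scope.

Other known limitations: the attribution estimator's component bias and
imprecision compression (above); Holm familywise calibration is checked
under independence-like nulls only; and the SVM AUCs on synthetic cohorts
are still somewhat cleaner than published clinical values even with the
competence trait.
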