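---
title: "Collinearity diagnostics and omitted-regressor bias in event-related fMRI designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collinearity diagnostics and omitted-regressor bias in event-related fMRI designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(midvif)
library(dplyr)
```

## The problem

In event-related task fMRI, the BOLD time series at a voxel is modeled by
a general linear model (GLM): `Y = X beta + e`, where the columns of `X`
are stimulus indicator functions convolved with a hemodynamic response
function (HRF). When trial components follow each other with little or no
separation — as in the Monetary Incentive Delay (MID) task, where Cue,
Fixation, Probe and Feedback abut with no inter-trial interval — the
convolved regressors overlap, and analysts face a dilemma: model every
component and accept correlated regressors, or omit components and risk
that their unmodeled signal is absorbed by — and biases — the regressors
that remain.

`midvif` provides the tools to reason about this trade-off
quantitatively:

* **contrast efficiency**, `1 / (c (X'X)^-1 c')`, the reciprocal of the
  unit-noise variance of a contrast estimate;
* the **traditional VIF (tVIF)** of a single regressor, the ratio of its
  parameter variance in the full model to its variance in a model
  containing only that regressor and an intercept;
* a **contrast-based VIF (cVIF)** that measures the variance penalty of a
  *contrast* relative to an ideal design with the same per-condition
  signal energy but no cross-condition overlap;
* a **synthetic MID task generator** reproducing the trial structure and
  behavioral statistics of the ABCD study's MID variant, so that every
  claim can be exercised without access to restricted scan data;
* a **bias simulation framework** that generates data from a fully
  specified ("Saturated") model and fits both that model and the reduced
  ("CueFeedback") model used in released ABCD analyses, measuring bias,
  type-I error and power per contrast; and
* **group-inference machinery**: precision-weighted run combination,
  percent-signal-change scaling, Cohen's d, a site-stratified sign-flip
  cluster-extent permutation test, and subject-outlier flagging.

## Why a contrast-based VIF

The tVIF is blind to a whole class of collinearity problems because it is
tied to one parameterization. Two statistically equivalent models — say,
condition regressors A and B versus their sum and difference — have
identical contrast variances for the same estimand, but very different
tVIFs. A design can present an "ideal" tVIF of 1 in one basis while the
contrast of scientific interest is badly inflated by overlapping
condition signals.

cVIF is defined in the *condition basis*. Let `G` be the Gram matrix of
the task columns after residualizing them against the intercept and
nuisance columns (drift should not be credited as usable signal energy).
For contrast weights `c`,

```
cVIF(c) = (c G^-1 c') / (sum_j c_j^2 / G_jj).
```

The numerator is the actual unit-noise variance factor of `c beta-hat`;
the denominator is what that factor would be in a reference design whose
Gram matrix is `diag(G)` — identical per-condition energy, zero overlap.
Three properties follow, each enforced by the test suite:

1. **Reparameterization invariance.** Mapping any invertible
   reparameterization back to the condition basis
   (`map_to_condition_basis()`) leaves cVIF unchanged, because
   `c (X'X)^-1 c'` is itself invariant.
2. **Reduction to tVIF.** For an elementary contrast selecting one
   centered column, cVIF equals the tVIF of that column.
3. **Values below 1 are possible** for difference contrasts on negatively
   correlated columns: negative correlation genuinely helps a difference.

We flag contrasts with cVIF above 5, the conventional benchmark for
single-regressor VIFs. On the synthetic MID task, the Saturated model
keeps all four primary contrasts (large win/loss cue versus neutral, and
the two within-valence hit-versus-miss feedback contrasts) comfortably
below that threshold, while the versus-baseline feedback contrasts sit
higher — the same qualitative picture reported for the real task. Adding
temporal derivatives to every Saturated regressor pushes cue-versus-
neutral cVIFs far above 20, which is why the Saturated model omits them.

```{r cvif-demo}
run <- simulate_mid_run(seed = 1)
design <- build_design(run, "saturated", drift_cutoff = 128)
report <- collinearity_report(design, make_contrasts(design))
report %>% filter(type == "contrast")
```

## The synthetic MID task

Each run has 50 trials, 10 per cue condition (LargeWin, SmallWin,
Neutral, LargeLoss, SmallLoss) in a seeded unconstrained permutation.
Within a trial, Cue (uniform 1.781–2.039 s), Fixation (uniform
1.5–3.666 s), Probe (adaptive, clamped to 0.150–0.500 s) and Feedback
(1.950 s minus the probe duration) are contiguous, and trials abut with
no inter-trial interval. Times are stored in seconds, 0-based from run
start.

The behavioral model is generative, not resampled:

* The latent response time is a shifted log-normal
  (`rt_shift + lognormal(rt_location, rt_scale)`), with the log-median
  decreasing linearly in the fixation duration so that longer
  preparation raises the hit probability — the slope is parameterized as
  `fixation_benefit`, the hit-probability gain per second of fixation at
  the distribution median. A trial is a Hit when the latent response
  falls inside the probe window; presses later than `rt_max` (1.581 s)
  are not recorded.
* Premature ("Too Soon") presses are independent of the response-time
  process, but their probability grows linearly with fixation time
  beyond a patience threshold (`too_soon_onset`, 2.15 s), normalized so
  the marginal rate is `p_too_soon_base` (7%). This is what produces the
  markedly longer fixations on Too Soon than Too Slow trials; a
  fixation-independent premature-press model cannot produce that gap.
  The main press still occurs on Too Soon trials when it falls within
  the recordable window, which yields the observed slightly shorter
  Too Soon response times without hard-coding them.
* The probe staircase targets 60% accuracy, adjusting every third trial
  by `staircase_step` (0.020 s, small against the probe range) based on
  the hit rate of the last six trials across all conditions. Note the
  asymmetric rule ("below target: lengthen, otherwise shorten") has its
  binomial equilibrium near a 58% hit rate rather than exactly 60% — the
  median of a Binomial(6, p) crosses 3.5 at p of about 0.58 — which is
  also why observed accuracies in this task sit slightly below target.

Defaults were calibrated once against the published behavioral summary
statistics of the task (57/36/7 percent Hit / Too Slow / Too Soon; probe
durations tens of milliseconds longer on hits; fixation about 60–160 ms
longer on hits; response times about 80–100 ms longer on misses; Too
Soon fixations about 0.7 s longer than Too Slow) and then frozen.

```{r behavior}
trials <- simulate_mid_trials(4000, seed = 42)
summarize_behavior(trials[-(1:200), ]) %>%
  filter(group %in% c("Hit", "Miss"))
```

What the generator does *not* emulate: session effects, learning or
fatigue drifts, condition-specific response strategies, real
pseudo-randomization constraints (the published description does not
specify them, so the permutation is unconstrained), scanner artifacts,
or temporally autocorrelated physiological noise. Tests passing on this
generator validate the estimators under the stated model, not the full
complexity of real data.

## Design matrices

Both fitted models use a canonical double-gamma HRF (peak 6 s,
undershoot 16 s, dispersions 1 s, undershoot ratio 1/6, 32 s kernel),
normalized to unit integral so that a sustained unit boxcar plateaus at
1. Convolution is evaluated semi-analytically from the cumulative
integral of the kernel on a microtime grid (`dt = tr/50`, with
`tr = 0.8` s): a boxcar's response is `H(t - onset) - H(t - onset -
duration)`, an impulse's is the kernel itself, and the temporal
derivative uses the analytic kernel derivative. This makes convolution
exactly linear in events, shift-equivariant on the microtime grid, and
continuous in the duration down to the impulse limit. Columns are
sampled at frame onsets (offset 0), a declared convention rather than an
estimated one.

* **CueFeedback** (the released-analysis model): impulses at the 5 cue
  and 10 feedback (cue type crossed with hit/miss) onsets, each paired
  with its temporal derivative — 30 task columns. Fixation, probe and
  response time are unmodeled.
* **Saturated**: boxcars for 5 cue, 5 fixation, 3 probe (win / loss /
  neutral), 1 response-time regressor (probe onset, response time as
  duration; trials without a recorded response time contribute nothing)
  and 10 feedback regressors — 24 task columns, no derivatives.

Feedback cells with no trials are dropped with a warning and recorded in
the design metadata; contrasts referencing dropped columns are skipped.
Nuisance structure is a per-run intercept plus a discrete-cosine
high-pass basis (order `floor(2 T / cutoff)`, cutoff 128 s); when runs
are concatenated the task columns stack over the union of names
(zero-filled where a run lacks a column) and intercept/drift blocks stay
run-specific, keeping nuisance orthogonal across runs.

## The bias simulation

Data are generated at a single synthetic voxel per subject from the
Saturated design: `Y = X beta_i + e`, independent Gaussian noise with
`sigma_w = 1` at `tr = 0.8` s, two 50-trial runs per subject
concatenated, the staircase carried across runs. Subject-level true
parameters are drawn as `Normal(mean, sigma_b^2)` with `sigma_b = 1.5`
around the scenario means; parameters with zero mean stay exactly zero
(a config flag lets them vary instead). The scenario presets set one
component at a time — cue (0.22 on large/small win), fixation (0.22),
probe (0.85 on win), response time (0.35), feedback (0.25 on large-win
hit and miss) — plus two compound settings merging all non-cue or all
non-feedback rows, and a global null. These effect sizes put
single-parameter group power near 80% at 500 subjects, and the implied
total-to-within SD ratios for the condition-difference contrasts,
`sqrt((c (X'X)^-1 c' + c c' * 2.25) / (c (X'X)^-1 c'))`, fall between
about 2.3 and 3.7 across synthetic subjects — inside the 2 to 4.2 band
such simulations aim for.

Each replicate dataset fits every subject by OLS under each model and
carries the per-subject contrast estimates to a two-sided one-sample
t-test at alpha 0.05 (the conventional level; the group alpha is a
declared choice). Reported per contrast and model: mean estimate, bias
(null contrasts), Monte-Carlo standard error, rejection rate (type-I
error or power), and an inflation flag from a one-sided exact binomial
test of the rejection rate against alpha at the 5% level — the
"inflated" criterion is thereby explicit rather than visual. Because
per-subject designs are fixed across replicates, the contrast estimator
rows `c'(X'X)^-1 X'` are precomputed once per subject; each replicate is
then a matrix-vector product, algebraically identical to refitting (the
suite tests this equivalence against `fit_ols()`).

```{r bias-demo, eval = FALSE}
designs <- simulate_subject_designs(60, seed = 2024)
sc <- simulation_scenario("fixation_win", n_subjects = 60,
                          n_reps = 150, seed = 11)
res <- run_scenario(sc, designs = designs)
res %>% filter(model == "cuefeedback", is_null)
```

The qualitative bias map this reproduces: unmodeled fixation signal
biases the cue-versus-neutral and feedback contrasts of the CueFeedback
model upward; unmodeled probe signal biases the feedback-versus-baseline
and feedback-versus-neutral contrasts; unmodeled response-time signal
biases feedback-versus-baseline; and the Saturated fit is unbiased
everywhere with nominal type-I error.

## Group inference

Per-run contrast estimates combine across runs by precision weighting
(`fixed_effects_combine()`), the minimum-variance linear unbiased
combination. For display, estimates scale to percent signal change by
the peak of the HRF response to a unit boxcar at the stimulus type's
mean duration (1.97 s cue, 1.67 s feedback in this task), divided by a
baseline (a configurable constant, default 100, in simulations that have
no mean image — making PSC a pure rescaling there). Group t statistics
convert to Cohen's d as `t / sqrt(n)`.

The group test is a one-sample t-map with cluster-extent FWER control:
threshold at `|t| > 3.1`, clusters by 6-connectivity (face-adjacent
voxels), and a null distribution of the maximum cluster size over
site-stratified sign flips — every subject within a site flips together,
so 13 sites give `2^13 = 8192` permutations, all enumerated when `2^S`
is within the cap and a seeded Monte-Carlo subset (identity flip always
included) otherwise. Positive and negative clusters contribute to a
single max-size null per flip, matching the singular "maximum cluster
size" of the procedure being emulated. The significance cut is the
95th percentile of the null with a ceiling rule — the smallest size with
at least 95% of the null at or below it — and observed clusters strictly
larger are significant; ties therefore resolve conservatively. Voxels
with zero variance across subjects are excluded from clustering.

Outlier screening (recommended when a contrast of interest has cVIF
above 5) marks voxels more than `k` (2 or 3) across-subject SDs from the
mean and flags subjects whose marked fraction exceeds a threshold;
zero-SD voxels never mark. With few subjects a gross outlier inflates
the SD enough to escape `k = 3` — the tests document this masking, and
`k = 2` is the safer screen in small samples.

## Numerical choices and problem sizes

* Rank handling: a design is singular when its QR rank drops or the
  smallest-to-largest singular value ratio falls below 1e-10; the error
  names the dependent columns.
* The microtime grid (`tr/50 = 16` ms) bounds interpolation error well
  below the 1e-3 relative tolerances used in the convolution tests.
* Frame counts per run are `floor(duration / tr)`; events may end up to
  one frame beyond the last sample (runs do not end frame-aligned).
* The test suite runs its simulation checks at reduced but stated sizes
  chosen to keep Monte-Carlo error well inside each tolerance: 60
  synthetic subjects shared across scenario checks, 150–1000 replicates
  per check, 500 null datasets of 12-cubed voxels for FWER calibration,
  and a 500-subject power check that recycles the 60-subject design pool
  (subjects still draw independent parameters and noise). The
  acceptance script regenerates 500 distinct subjects.
* Unbiasedness of the generating-model fit is asserted two ways: exactly
  (noiseless recovery of arbitrary parameter vectors) and by Monte
  Carlo with a family-wise 3.6-SE bound across the seven correlated
  contrasts.

## Known limitations

The simulation noise is white by design; AR(1)-prewhitening of real runs
is out of scope, and the OLS variance formulas assume independence.
NIfTI volumes are handled as plain R arrays (any reader, e.g. RNifti,
can supply them); no spatial preprocessing is provided. The Fig-style
toy cVIF magnitudes from the motivating literature (17, 26, 4) depend on
unpublished toy timings and are asserted only directionally. Real
pseudo-randomization constraints of the task are unknown and therefore
not imposed. The three-way Correct / Too Soon / Too Slow feedback model
that the behavioral asymmetries motivate is deliberately not implemented.
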