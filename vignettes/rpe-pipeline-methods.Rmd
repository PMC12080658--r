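---
title: "Model-based imaging of reward prediction errors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based imaging of reward prediction errors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpepipe)
```

rpepipe implements a complete model-based fMRI pipeline for probabilistic
reward learning: a two-alternative monetary reward task, a Q-learning model
of trial-wise choice with maximum-likelihood fitting, behavioural and
head-motion quality control, a first-level GLM with a reward-prediction-error
(RPE) parametric modulator, and group-level symptom-correlation inference
with permutation-based cluster correction. A synthetic-cohort generator with
planted ground truth makes every stage testable end to end without any
imaging data.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic data do and do not emulate.

## The task

Participants repeatedly choose between two abstract stimuli and receive
probabilistic monetary feedback. A session has 10 blocks of 16 trials, each
block presenting one fixed stimulus pair. Pairs at block positions
1, 3, 4, 5 and 7 are *rewarded* pairs: one stimulus wins on 80% of trials,
the other on 20%. The remaining five are *bivalent* pairs with 50%/50%
contingencies, so there is nothing to learn and they serve as a
non-learning control condition. A 48-trial practice phase precedes the
160 main trials.

Each trial shows the pair for 2.5 s (the response window), then 1 s of
feedback, then a fixation interval drawn from an exponential distribution
truncated to [1.0, 6.5] s. The exponential rate is calibrated by
root-finding so that the truncated mean is exactly 2.0 s
(`rpepipe:::jitter_rate()` ≈ 0.9747); the task's event timing is therefore
jittered with the long right tail that makes event-related designs
estimable.

`generate_schedule()` pre-samples the outcome *both* stimuli would deliver
on every trial (`outcome_if_A`, `outcome_if_B`), so a simulated or observed
choice just indexes into the schedule; the counterfactual outcome is
retained. This makes schedules reusable across agents and makes the
realized contingencies auditable.

## The learning model

Each stimulus carries an expected value $EV$, reset to 0 at the start of
every block (each block introduces a fresh pair). After the outcome
$R_t \in \{0, 1\}$ of a chosen stimulus, only the chosen stimulus updates by
the delta rule

$$\delta_t = R_t - EV_t, \qquad EV_{t+1} = EV_t + \alpha\,\delta_t,$$

where $\alpha \in [0, 1]$ is the learning rate and $\delta_t$ is the reward
prediction error. Choices follow a softmax on the EV difference with
temperature $\beta$:

$$P(A_t) = \frac{1}{1 + \exp\{-(EV_{A,t} - EV_{B,t})/\beta\}}.$$

$\beta$ is used as a *divisor* (temperature semantics): higher $\beta$
means more exploratory, closer-to-random choice. The degenerate case
$\alpha = 0$ leaves all EVs at 0 and predicts probability $1/2$ on every
trial, a useful exact reference point (the 160-trial negative
log-likelihood is then $160\ln 2$).

## Fitting

`fit_subject()` minimizes the choice-sequence negative log-likelihood over
$(\alpha, \beta)$ with bounded L-BFGS-B from multiple Latin-hypercube start
points (default 10, plus the box midpoint), bounds $\alpha \in [0, 1]$ and
$\beta \in [0.01, 10]$. The lower $\beta$ bound keeps the softmax finite;
the upper bound is far above empirically plausible temperatures (~0.3).
Ties between starts are broken by lowest NLL, then by smaller $\beta$.
Per-trial probabilities are floored at $10^{-12}$ before taking logs, so a
single surprising choice cannot produce an infinite objective. Missed
trials contribute nothing to the likelihood and do not update EVs.

Two structural facts make dense likelihood surfaces cheap
(`nll_surface()`): the EV path depends on $\alpha$ only ($\beta$ enters
only through the softmax), and blocks are independent. The surface over an
$\alpha$-grid × $\beta$-grid therefore costs one EV sweep per $\alpha$,
which is what the test suite uses to verify that the optimizer always
reaches the grid optimum.

Parameter recoverability is a first-class experiment
(`recoverability_experiment()`): simulate agents at known parameters, refit,
and report per-parameter correlation, bias and RMSE. At the task's length
(160 trials), bias at typical parameter values is below 0.02 and
true–estimated correlations are ~0.85 ($\alpha$) and ~0.73 ($\beta$) over
dispersed truths — adequate for group-level correlational use, with
substantial per-subject shrinkage-free noise (RMSE ≈ 0.13).

Model fit is summarized as the RMSE between made choices (coded 1) and
their model probabilities, `model_fit_rmse()`: 0 is perfect prediction and
0.5 is the chance model. Group-level analyses use the cross-subject
*median* parameters (`group_median_params()`) to build every subject's RPE
regressor from the same model, so that between-subject differences in the
imaging regressor reflect choices and outcomes, not noisy per-subject
parameter estimates.

## Behavioural and motion quality control

Three filters, each a pure function returning a keep flag with its
criterion value (`qc_report()` combines them):

- **Learning** (`learning_exclusion()`): keep if the optimal stimulus was
  chosen on at least 50% of the last eight trials of the rewarded pairs,
  pooled over the five rewarded blocks (40 trials). Exactly 50% (20/40)
  keeps; missed trials count as non-optimal. A stricter per-block reading
  is also reported.
- **Responses** (`response_exclusion()`): exclude if more than 10% of main
  trials are missing or anticipated (reaction time < 100 ms). Exactly 10%
  (16/160) keeps.
- **Motion** (`motion_exclusion()`): exclude if maximum absolute
  displacement exceeds 3.0 mm or mean absolute displacement exceeds
  0.3 mm. Values exactly at a threshold keep.

The boundary conventions (strict "less than" / "more than") are fixed and
asserted by tests, since off-by-one conventions at these boundaries change
cohort composition.

## First-level GLM

The haemodynamic response is modelled as a gamma density with mean lag 6 s
and SD 3 s (shape 4, scale 1.5; mode at 4.5 s), discretized at a microtime
resolution of TR/16 and normalized to unit sum, so convolving a constant
neural signal leaves its level unchanged (`gamma_hrf()`).

`build_design()` produces, for 440 volumes at TR = 2 s:

- four condition regressors — stimulus and feedback events for rewarded and
  bivalent pairs (durations 2.5 s and 1 s);
- the RPE parametric modulator: a feedback-locked regressor whose amplitude
  is the trial's model-derived RPE, mean-centered across trials so it is
  decorrelated from the feedback main effect;
- temporal derivatives of the five task regressors;
- six motion parameters, unconvolved.

Missed trials generate no feedback event and no modulator mass.
`fit_first_level()` adds an intercept, fits voxelwise OLS (matrix form, one
QR decomposition for all voxels), and converts contrast t-values to z-scores
through a log-space stable normal/t quantile mapping (`t_to_z()`), which
stays finite far into the tails. Rank-deficient designs are an error, not a
silent drop.

White noise is the generator's (and estimator's) working model; the OLS
estimator is unbiased under temporal autocorrelation but its standard
errors would be optimistic on real, autocorrelated BOLD — one reason the
group stage relies on permutation rather than parametric voxel variances.

## Group inference

Subject-level RPE beta maps are stacked (subjects × voxels) and analysed by
voxelwise OLS: a one-sample/group design (`group_glm_map()`) or a
symptom-score slope with covariates (`symptom_correlation_map()`; age, sex
and premorbid IQ by default, scores standardized, covariates mean-centered).
This single-stage OLS replaces a two-stage mixed-effects estimator;
first-level variance maps are not propagated, a recorded limitation that
permutation inference tolerates.

Cluster correction (`cluster_inference()`) thresholds the z map (default
z > 3.1, direction-specific), labels connected components (26-connectivity
by default, 6 optional; labeling is verified against an independent
flood-fill oracle), and compares each cluster's size with the permutation
null distribution of the *maximum* cluster size: sign-flipping of residual
maps for one-sample tests, score permutation for correlation tests, with
the corrected p-value $(1 + \#\{\text{null} \ge s\}) / (n_{\mathrm{perm}} + 1)$.
Permutation replaces Gaussian-random-field correction: it is exact under
exchangeability, needs no smoothness estimate, and behaves correctly on the
small grids used here.

A practical note on calibrating false-positive rates by simulation: on
*voxelwise-independent* noise the maximum cluster size is an extremely
discrete statistic (almost all supra-threshold voxels are singletons), so
corrected rates sit far below nominal — conservative, not anti-conservative.
The family-wise error calibration test therefore uses spatially smoothed
null maps (Gaussian FWHM 12 mm at 3.5 mm voxels) with a matched
cluster-forming threshold of z > 2.3 on a 12×12×8 grid, where the null
distribution of cluster sizes is rich enough for the empirical rate to sit
at its nominal 5%. Real BOLD maps are spatially smooth, so this is the
regime that matters.

`roi_summary()` gives the complementary region-of-interest view: per-subject
mean betas in a mask, with an optional covariate-adjusted group comparison.

## The synthetic cohort

`cohort_spec()` + `generate_cohort()` produce a full study-shaped dataset.
Defaults describe the emulated study conditions:

- 78 patients and 43 controls;
- learning rate drawn from truncated normals on [0, 1]: 0.45 ± 0.20
  (controls) vs 0.39 ± 0.28 (patients); temperature on (0.01, 10]:
  0.29 ± 0.19 vs 0.30 ± 0.27. With these means patients learn slightly
  less, so their mean optimal-choice rate sits below controls';
- per-subject choices simulated on a fresh schedule with a 2% miss rate;
- delusion-severity and referentiality scores for patients from truncated
  normals on their instruments' ranges (0–24 and 0–10), correlated at 0.5
  through a Gaussian copula; disorganization, negative-symptom and
  antipsychotic-dose covariates;
- head-motion series as smoothed random walks, rescaled so that a 12/103
  fraction of subjects violates the motion thresholds;
- a planted imaging effect in two axis-aligned regions ("striatum_like",
  "frontal_like" — testing labels, no anatomical claim) on a 16×16×12 grid:
  voxelwise RPE response amplitude
  $1.0 + (-0.5) \cdot z(\text{delusion score})$ for patients (baseline 1.0
  for controls), zero elsewhere;
- BOLD = subject's own generating design × true betas + white noise
  (SD 1), 440 volumes at TR 2 s, synthesized on demand from per-subject
  seeds so a cohort object stays small.

The generating model uses each subject's *true* parameters for the RPE
modulator while the analysis pipeline replays choices at the pooled median
parameters — a realistic model mismatch that the planted effect must (and
does) survive.

What the generator deliberately does **not** emulate: anatomy and
registration, physiological noise and scanner drift, temporal
autocorrelation, reaction-time structure, and realistic symptom-score
distributions (only their ranges and a moderate-severity location are
used). Passing tests therefore demonstrate that the *pipeline logic* is
correct — the estimators recover what was planted at realistic sizes and
noise — not that real acquisitions satisfy the estimators' assumptions.

`run_pipeline()` chains fitting → median parameters → per-subject design +
first-level GLM → patient delusion-slope map → negative-direction cluster
correction, and `ground_truth_report()` scores the result against the
planted truth (parameter recovery, Dice overlap of significant clusters
with planted regions, sign agreement).

## Numerical choices and problem sizes

- Likelihood probability floor $10^{-12}$; optimizer tie-break tolerance
  $10^{-9}$ on NLL; boundary flag tolerance $10^{-6}$.
- t→z conversion via `qnorm(pt(..., log.p = TRUE), log.p = TRUE)`, stable
  beyond |z| ≈ 8 where naive CDF round-tripping saturates.
- Cluster p-values use the add-one permutation estimator, so the smallest
  attainable p is $1/(n_{\mathrm{perm}}+1)$.
- Degenerate inputs error early: all-missed subjects, constant score
  vectors, rank-deficient designs, empty masks, infeasible truncations.
- The test suite runs the pipeline at the full default cohort
  (121 subjects, 16×16×12, 440 volumes, 500 permutations), calibrates
  family-wise error over 200 null cohorts of 15 smoothed maps
  (150 permutations each), and sizes recovery experiments at 100–300
  agents; optimizer starts are reduced (5–6) in the large batch runs,
  which multi-start validation shows is ample for this smooth
  two-parameter surface.
- All simulations are seeded; cohort generation restores nothing silently —
  the same seed gives a byte-identical cohort.

## Known limitations

- Single-stage OLS at the group level ignores first-level uncertainty.
- White-noise first-level model (no prewhitening); see above.
- The softmax uses the two-stimulus logistic form; the model does not
  generalize as-written to more than two options per pair.
- Median-parameter regressor building is a choice, not an estimate of a
  hierarchical model; it trades per-subject flexibility for cross-subject
  comparability.
- Cluster peak coordinates are reported in voxel indices; no atlas or
  template space is implied.
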