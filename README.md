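# rpepipe

Model-based fMRI of reward prediction errors in probabilistic reward
learning — task simulation, reinforcement-learning model fitting,
behavioural/motion quality control, first-level GLM with an RPE parametric
modulator, and group-level symptom-correlation inference with permutation
cluster correction. A synthetic-cohort generator with planted ground truth
makes the whole chain testable end to end without any imaging data.

It is written for computational-psychiatry and decision-neuroscience
researchers who analyse two-alternative probabilistic reward tasks: people
who need trial-wise model regressors for imaging, transparent exclusion
rules, and inference whose false-positive behaviour they can check by
simulation.

## The model

On each trial of a block, the chosen stimulus's expected value is updated
by the delta rule

    δ_t = R_t − EV_t,        EV_{t+1} = EV_t + α · δ_t

with learning rate α ∈ [0, 1] and reward R_t ∈ {0, 1}; EVs reset at block
boundaries. Choices follow a softmax on the EV difference with temperature
β (higher β = more exploratory):

    P(choose A) = 1 / (1 + exp{ −(EV_A − EV_B) / β })

(α, β) are estimated per subject by maximum likelihood (multi-start bounded
L-BFGS-B). The trial-wise prediction errors δ_t, replayed at the pooled
median parameters, become the feedback-locked parametric modulator of the
first-level GLM; group inference then maps where the RPE response covaries
(negatively) with delusion severity, with cluster-level family-wise error
controlled by score-permutation of the maximum cluster size.

## Worked example

Simulate one subject, fit the model, and check the behavioural filters:

```r
library(rpepipe)

sched <- generate_schedule(seed = 101, n_practice = 0)
rec   <- simulate_agent(sched, alpha = 0.45, beta = 0.29, seed = 102)
fit   <- fit_subject(rec, sched, seed = 103)
fit
#> Q-learning ML fit: alpha = 0.427, beta = 0.342, nll = 86.54 (160 trials)

tidy(fit)
#> # A tibble: 2 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 alpha    0.427
#> 2 beta     0.342

learning_exclusion(rec, sched)
#> # A tibble: 1 × 3
#>   criterion keep  keep_per_block
#>       <dbl> <lgl> <lgl>
#> 1      0.75 TRUE  TRUE
```

The simulated subject (true α = 0.45, β = 0.29) is recovered at
α̂ = 0.43, β̂ = 0.34 from 160 choices, and chose the optimal stimulus on
75% of the late rewarded trials, passing the learning filter
(threshold: ≥ 50%).

Run the full pipeline on a synthetic cohort with a planted negative
delusion–RPE association (amplitude 1 − 0.5·z(delusion score) inside two
designated regions):

```r
spec <- cohort_spec(n_patients = 40, n_controls = 20, grid = c(10, 10, 8),
                    n_volumes = 300)
co  <- generate_cohort(spec, seed = 104)
res <- run_pipeline(co, n_perm = 300, seed = 105)

res$clusters[, c("label", "size_voxels", "peak_z", "p_corrected")]
#> # A tibble: 2 × 4
#>   label size_voxels peak_z p_corrected
#>   <int>       <int>  <dbl>       <dbl>
#> 1     1          11  -4.71     0.00332
#> 2     2          11  -4.72     0.00332

ground_truth_report(co, res)
#>   alpha_cor alpha_bias beta_cor beta_bias  dice n_significant_clusters sign_correct
#> 1     0.868     0.0316    0.648    0.0534 0.657                      2         TRUE
```

The pipeline fits all 60 subjects, builds each subject's RPE-modulated
design at the median parameters, estimates voxelwise first-level betas,
regresses the patients' RPE beta maps on their delusion scores (adjusting
for age, sex and premorbid IQ), and finds two negative clusters surviving
permutation correction (corrected p ≈ 0.003). The ground-truth report
confirms they are the planted regions: Dice overlap 0.66, correct
(negative) sign, and true-vs-fitted parameter correlations of 0.87 (α) and
0.65 (β). At the full default cohort (78 patients, 43 controls, 16×16×12
grid, 440 volumes) the detected clusters coincide exactly with the planted
regions.

The methods vignette (`vignettes/rpe-pipeline-methods.Rmd`) documents the
task, the model, every filter threshold, the GLM and permutation details,
and what the synthetic data do and do not emulate.

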