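# delaymle

Delay-aware maximum-likelihood state estimation for visuo-proprioceptive
integration: a forward model, a task simulator, and an analysis pipeline for
studying when the nervous system should — and behaviourally does — stop
integrating sensory feedback across modalities.

## The science

Estimates of limb position from vision and proprioception arrive with
different feedback delays (≈70 ms vs ≈20 ms). While the limb is stationary,
combining the two by reliability weighting (maximum-likelihood estimation)
is strictly beneficial:

    mu_B = (sigma_P^2 * mu_V + sigma_V^2 * mu_P) / (sigma_V^2 + sigma_P^2)
    sigma_B^2 = sigma_V^2 * sigma_P^2 / (sigma_V^2 + sigma_P^2)

While the limb moves at speed `v`, each channel reports the position from
`tau_i` seconds ago, so the integrated estimate lags the ideal (zero-delay)
one by the reliability-weighted mean delay:

    offset = v * (sigma_P^2 * tau_V + sigma_V^2 * tau_P) / (sigma_V^2 + sigma_P^2)

The package scores that lag by the intersection-over-union of the delayed
and ideal bimodal Gaussians — the probability that the delayed estimate
still falls where the ideal one would. It is 1 when stationary, decays with
speed, and decays more slowly when sensory uncertainty is high, predicting
that only high-variance individuals keep integrating during movement.

Around that model the package provides:

* `run_sweep()` — the probability over grids of speed, delay, and variance;
* `sample_trajectory()`, `extract_endpoint()`, `extract_midpoint()` —
  minimum-jerk Bezier arc trajectories at 1 kHz and the velocity-threshold
  scoring rules of the static and dynamic estimation tasks;
* `make_cohort()`, `simulate_experiment()` — synthetic cohorts and full
  randomised trial tables for the static/dynamic conflict experiments
  (6 cm visual–proprioceptive conflicts, the tasks' block structures,
  counterbalanced sides);
* `bias_fit()` — the model-fit object: signed report errors, per-subject
  integration biases against unimodal baselines, estimated integration
  weights, predicted bimodal variances, sign-flip permutation tests, and
  the bias-on-variance regression; with `print`, `summary`, `coef`, and
  `plot` methods, plus `group_inference()` for the static-vs-dynamic
  task contrast.

A thin command-line wrapper (`inst/exec/delaymle`) exposes `sweep`,
`simulate-cohort`, `analyze`, and `end-to-end` over the same functions.

## Worked example

```r
library(delaymle)

# How fast can you move before the bimodal estimate stops being useful?
run_sweep(speed = c(0, 0.05, 0.187), tau_v = 0.07, tau_p = 0.02,
          var_v = 1e-4, var_p = 1e-4)
#>   speed_mps tau_v_s tau_p_s var_v_m2 var_p_m2 offset_m probability
#> 1     0.000    0.07    0.02    1e-04    1e-04 0.000000   1.0000000
#> 2     0.050    0.07    0.02    1e-04    1e-04 0.002250   0.7755538
#> 3     0.187    0.07    0.02    1e-04    1e-04 0.008415   0.3810468
```

At rest the delayed and ideal estimates coincide (probability 1). At the
task's 0.187 m/s peak speed, the integrated estimate lags by 8.4 mm and
only ~38% of its mass still overlaps the ideal estimate — integrating has
become a liability.

```r
# Simulate a static-task cohort that integrates by MLE, and analyse it
cohort <- make_cohort(22, seed = 1)
trials <- simulate_experiment(experiment_design("exp1_static"), cohort,
                              seed = 101)
fit <- bias_fit(trials, seed = 201)
fit
#> Integration-bias fit: exp1_static (static task), 22 subjects
#>   VP_V bias: +0.0318 m (p = 9.999e-05, sign-flip, 10000 perms)
#>   VP_P bias: +0.0285 m (p = 9.999e-05, sign-flip, 10000 perms)
#>   max bias ~ predicted bimodal variance: slope -62.3, r^2 0.065, p = 0.2532
```

Reports in bimodal trials are pulled ~3 cm toward the cue subjects were
told to ignore — half the 6 cm conflict, exactly what reliability weighting
with roughly equal variances predicts (mean estimated weight ≈ 0.5) — and
the flat bias–variance relationship is the expected static-task pattern. A
dynamic-task cohort simulated with `w_dynamic = 1` instead shows biases
statistically indistinguishable from zero, and `group_inference()` on the
pair recovers the task-by-condition interaction.

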