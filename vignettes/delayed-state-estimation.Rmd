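---
title: "Delay-aware multisensory state estimation: model, simulation, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-aware multisensory state estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaymle)
```

## The problem

Estimating where one's limb currently is requires sensory feedback, and the
two feedback channels most relevant for the arm — vision and proprioception —
arrive with different latencies (cortical feedback delays are roughly 70 ms
for vision and 20 ms for proprioception). When the limb is stationary, this
does not matter: the classical reliability-weighted (maximum-likelihood)
combination of the two channels reduces uncertainty and is the normative
strategy. When the limb is moving, however, each channel reports where the
limb *was*, not where it *is*, and the two channels disagree with each other
as well as with the present. This package formalises that problem, generates
synthetic behavioural cohorts for the static and dynamic conflict tasks that
probe it, and analyses the resulting trial tables.

## The model

Each channel $i \in \{V, P\}$ contributes a Gaussian position belief
$\mathcal{N}(\hat\mu_i, \sigma_i^2)$. On a constant-velocity path with speed
$\nu$, the estimate available at time $t$ is the true position at $t -
\tau_i$:

$$\hat\mu_i = \mu + \nu\,(t - \tau_i),$$

implemented by `delayed_unimodal_mean()`. Reliability-weighted combination
(`mle_combine()`) gives

$$\hat\mu_B = \frac{\sigma_P^2\,\hat\mu_V + \sigma_V^2\,\hat\mu_P}
  {\sigma_V^2 + \sigma_P^2},\qquad
  \hat\sigma_B^2 = \frac{\sigma_V^2 \sigma_P^2}{\sigma_V^2 + \sigma_P^2}.$$

The delayed bimodal estimate therefore lags the ideal (zero-delay) one by

$$\Delta = \nu\,\frac{\sigma_P^2 \tau_V + \sigma_V^2 \tau_P}
  {\sigma_V^2 + \sigma_P^2},$$

the reliability-weighted mean delay times the speed
(`bimodal_offset_error()`). The delay changes no variance term — the model
assumes the percept does not degrade over time and that uncertainty does not
scale with speed — so the actual and ideal bimodal distributions differ only
in mean.

How bad is a lag of $\Delta$? We score it by the intersection-over-union of
the two Gaussians (`overlap_probability()`): the area under both curves
(found via the between-means crossing point $c$, as
$P[X_{\text{actual}} > c] + P[X_{\text{ideal}} < c]$), normalised by the
area under their upper envelope ($2$ minus the intersection). For the
equal-variance case that arises in the model, the closed form is
$\text{overlap} = 2\,\Phi(-|\Delta|/2\sigma)$. The resulting probability is
1 for a stationary limb and decays monotonically with speed — and decays
*more slowly* when the sensory variances are large, which is the model's
key individual-differences prediction: only subjects with wide bimodal
estimates can afford to keep integrating while moving.

```{r}
run_sweep(speed = c(0, 0.05, 0.187), tau_v = 0.07, tau_p = 0.02,
          var_v = 1e-4, var_p = 1e-4)
```

### Numerical choices

* Equal variances use the exact $\Phi$ closed form; unequal variances solve
  the log-density quadratic and keep only the between-means root (the outer
  crossing of unequal-variance Gaussians carries negligible mass in the
  regimes swept here, and the two-tail summation is defined with respect to
  the between-means crossing). Coincident means are flagged `degenerate`
  and return probability 1.
* Default delays $\tau_V = 70$ ms, $\tau_P = 20$ ms (primate cortical
  feedback latencies); default speed grid 0–0.5 m/s, bracketing comfortable
  reach speeds. Both are configurable; the sweep bounds are a package
  choice, not a measured fact.
* All positions are in metres, times in seconds, variances in m²;
  probabilities are unitless.

## Trajectories

The tasks move the hand (or a cursor) along symmetric three-control-point
Bezier arcs: 15 cm forward, midpoint 3 cm off the midline, traversed in
1600 ms. "Bell-shaped velocity profile" is implemented as the standard
minimum-jerk profile over *arc length*
(`minimum_jerk_progress()` + `sample_trajectory()`), whose peak rate is
$1.875\,L/T$. On the stated geometry ($L \approx 0.1647$ m, $T = 1.6$ s)
that gives a peak speed of $\approx 0.193$ m/s — close to, but not exactly,
the 0.187 m/s the task description quotes; no standard profile family
reproduces that printed value on this geometry, so the package validates
peak speed against the analytic $1.875\,L/T$ instead.

Endpoint and midpoint scoring mirror the recorded-kinematics rules:
`extract_endpoint()` returns the position at the last sample of the *first*
window during which speed (centred finite differences at 1 kHz) stays below
threshold for the full hold duration (0.06 m/s for 500 ms in the static
task; 0.05 m/s for 2000 ms in the dynamic task) — i.e. the first genuine
stop, before any corrective movement. `extract_midpoint()` linearly
interpolates the x-position at the first upward crossing of $y = 7.5$ cm;
later re-crossings are ignored. Passive transport uses cubic Bezier paths
with interior control points drawn uniformly from the start–end bounding
box inflated 6 cm laterally (`random_passive_path()`); the true sampling
distribution of those paths is not documented anywhere, so the uniform box
is a package choice.

The coordinate frame places the origin at the trial start, $+y$ away from
the body, $+x$ rightward.

## The synthetic cohort

`make_cohort()` draws per-subject parameters from a population model and
`simulate_experiment()` produces full randomised trial tables with the
tasks' block structures (static: 120 baseline unimodal trials, then
24 V + 24 P + 60 VP~V~ + 60 VP~P~; dynamic: 60 baseline, then
20 + 20 + 60 + 60), a 6 cm cue conflict in every design, and modality–side
pairing alternated across subjects.

Reports live directly on the discrepancy axis (y for the static task of the
first experiment, x elsewhere); full 2-D trajectories are optional
decoration. The generative report model is:

* unimodal: $r = \text{cue} + b_m + \varepsilon$,
  $\varepsilon \sim \mathcal{N}(0, \sigma_m^2 + \sigma_{\text{motor}}^2)$;
* bimodal: $r = w\,\text{cue}_{\text{att}} + (1-w)\,\text{cue}_{\text{ign}}
  + b_{\text{att}} + \varepsilon$, with noise variance
  $w^2\sigma_{\text{att}}^2 + (1-w)^2\sigma_{\text{ign}}^2 +
  \sigma_{\text{motor}}^2$ (the variance of a $w$-weighted average of the
  two noisy unimodal estimates plus execution noise).

The static weight is the subject's reliability weight
($w = \sigma_{\text{ign}}^2 / (\sigma_V^2 + \sigma_P^2)$), so the expected
signed bias toward the ignored cue is $(1-w)\times 6$ cm. The dynamic
weight is $w_{\text{dyn}} = \text{clip}(1 - k\,\hat\sigma_B^2,\, 0,\, 1)$:
$k = 0$ (the default) gives purely unimodal dynamic reports — the
behavioural finding the model predicts — while $k > 0$ grades dynamic
integration by bimodal variance, emulating the observed
individual-differences correlation. In tests that exercise that mechanism
we use $k = 3000\ \text{m}^{-2}$, which spans dynamic biases over roughly
0–2 cm across a cohort.

Population defaults, chosen once as field-typical values: unimodal report
SD 1 cm per modality (log-normal across subjects, $\text{sdlog} = 0.5$),
motor noise SD 4 mm, constant per-subject sensory biases SD 5 mm,
recalibration drift 0, side offset 0. Sensory recalibration, when enabled,
is a linear per-trial drift of static-task unimodal reports toward the
other modality's cue during the mixed block only. The side effect seen with
lateral targets is a fixed per-subject additive offset (a biomechanical
nuisance); because each subject's modality stays on one side, baseline
subtraction removes it from biases, which is exactly how a nuisance
covariate should behave.

What the generator does *not* emulate: working-memory decay, attention
lapses, trial-by-trial Bayesian recalibration dynamics, joint-space
biomechanics, or non-compliant participants. Passing tests therefore show
that the *pipeline* recovers what this generative model puts in — not that
human data obey the model.

## The analysis

`bias_fit()` is the package's fitting function. From a trial table it
computes:

* signed report errors (`report_error()`): $(r - \text{cue}_{\text{att}})$
  oriented positive toward the other modality's cue; unimodal trials use
  the other modality's standard cue for that subject as the sign reference,
  recovered from the subject's own unimodal trials so that
  counterbalancing needs no bookkeeping;
* baseline means and unbiased variances per modality from block 1
  (`baseline_stats()`);
* per-subject condition biases — mean bimodal error minus the corresponding
  baseline mean (`compute_bias()`) — plus `max_bias` (the larger of the two,
  regardless of modality), the predicted bimodal variance
  (`predicted_bimodal_variance()`, algebraically identical to
  `mle_combine()`'s variance), and estimated integration weights
  $\hat w = 1 - \text{bias}/6\,\text{cm}$;
* sign-flip permutation tests of each condition bias against zero;
* the block-2-minus-block-1 unimodal shift (`unimodal_shift()`); and
* the OLS regression of `max_bias` on predicted bimodal variance
  (`bias_variance_regression()`), reported with and without the single
  largest-residual subject, since one outlying participant can carry or
  mask this correlation at typical sample sizes.

Group-level inference deliberately replaces mixed-effects regression with
subject-level summary statistics and sign-flip permutation tests
(`sign_flip_test()`, `group_inference()`): the scientific contrasts are
within-subject condition means, for which sign-flip inference is
assumption-light (exact under symmetry) and exactly testable. When
$2^n \le$ the permutation budget the test enumerates all sign patterns and
is exact; otherwise it uses the add-one Monte-Carlo estimate
$(1 + \#\{|T^*| \ge |T|\})/(B+1)$. Below $n = 5$ it warns that attainable
p-values are coarse. The task-by-condition interaction is tested by
sign-flipping each subject's static-minus-dynamic mean bias when the
cohorts share subjects, and by label permutation otherwise (flagged).
Exactly two planned contrasts are tested per task and no multiplicity
correction is applied; the printout says so.

A known property of the `max_bias` statistic: the maximum of two noisy
zero-mean bias estimates has positive expectation proportional to the
subject's sampling SD, which itself grows with the subject's sensory
variances. Under a null (non-integrating) cohort this induces a small
positive slope of `max_bias` on predicted bimodal variance and a mildly
inflated false-positive rate relative to the nominal 5% (the test suite's
null-cohort check measures this rate directly).
This is intrinsic to using the largest mean bias and applies equally to
analyses of real data with this statistic; it is not corrected here because
the point of the pipeline is to replicate that analysis faithfully.

An optional peak-velocity adjustment (pooled OLS slope, centred) can be
applied to report errors before bias computation; it is off by default for
synthetic data, whose velocities are pure nuisance draws.

## Problem sizes and reproducibility

Simulated checks use the tasks' own scales: cohorts of 20–23 subjects,
60 bimodal trials per condition, 10,000 permutations; the calibration check
of permutation p-values uses 500 null cohorts of 20 subjects at 2,000
permutations each, and the null-slope check uses 100 cohorts of 23. Every
stochastic function takes a `seed` argument and restores the caller's RNG
state, so the same configuration reproduces byte-identical trial tables
and result files (`run_pipeline()` embeds the configuration, derived
seeds, and package version in a provenance block of every `results.json`).

## Limitations

* The forward model is a snapshot in time: constant speed, no time-varying
  profiles inside the model, no Kalman-filter/dynamic-Bayesian machinery,
  no efference copy — it addresses passive movement only.
* The generator's parameters are population-plausible, not fitted to any
  dataset; quantities that depend on them (e.g. absolute bias variances)
  should be read as demonstrations, not predictions.
* Mixed-effects analogues (random slopes, small-sample dof corrections,
  post hoc families) are intentionally out of scope; `group_inference()`
  answers the same scientific questions by permutation.
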