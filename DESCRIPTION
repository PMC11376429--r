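Package: delaymle
Title: Delay-Aware Maximum-Likelihood State Estimation for Visuo-Proprioceptive Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models, simulates, and analyses feedback-based limb state
    estimation under visual and proprioceptive sensory delays. Implements a
    delay-augmented maximum-likelihood (reliability-weighted) cue-combination
    model and its Gaussian intersection-over-union accuracy statistic, with
    parameter sweeps over movement speed, delay, and sensory variance;
    minimum-jerk Bezier trajectory generation with velocity-threshold endpoint
    and midpoint extraction; a synthetic-cohort generator for static and
    dynamic visuo-proprioceptive conflict tasks; and an analysis pipeline
    computing report errors, integration biases, predicted bimodal variances,
    and sign-flip permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
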