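#' Population configuration for synthetic cohorts
#'
#' Defines the population distributions from which per-subject parameters are
#' drawn. Unimodal report standard deviations are log-normally distributed
#' around `sd_v` / `sd_p` (on the variance scale), motor execution noise is a
#' constant additional variance on every report, and constant per-subject
#' sensory biases are Gaussian around zero.
#'
#' @param sd_v,sd_p Population-typical unimodal report standard deviations in
#'   metres (default 0.01 each: ~1 cm endpoint scatter per modality).
#' @param sdlog Log-scale spread of the per-subject variances (default 0.5).
#' @param motor_sd Motor noise standard deviation in metres added to every
#'   report (default 0.004).
#' @param bias_sd Standard deviation of per-subject constant sensory biases in
#'   metres (default 0.005).
#' @param k_dynamic Susceptibility coefficient linking dynamic-task
#'   integration weight to predicted bimodal variance:
#'   `w_dynamic = clip(1 - k_dynamic * var_bimodal, 0, 1)` (1/m^2; default 0,
#'   i.e. purely unimodal dynamic reports).
#' @param recalib_rate Per-trial recalibration drift of unimodal reports
#'   toward the other modality's cue in static mixed blocks, in metres per
#'   trial (default 0).
#' @param side_offset_sd Standard deviation of the per-subject side-dependent
#'   (biomechanical) report offset in metres, applied in designs with lateral
#'   targets (default 0).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(sd_v = 0.01, sd_p = 0.01, sdlog = 0.5,
                          motor_sd = 0.004, bias_sd = 0.005,
                          k_dynamic = 0, recalib_rate = 0,
                          side_offset_sd = 0) {
  vals <- list(sd_v = sd_v, sd_p = sd_p, sdlog = sdlog, motor_sd = motor_sd,
               bias_sd = bias_sd, k_dynamic = k_dynamic,
               recalib_rate = recalib_rate, side_offset_sd = side_offset_sd)
  ok <- vapply(vals, is_number, logical(1L))
  if (!all(ok))
    stop_delaymle("all cohort_config values must be single finite numbers",
                  "delaymle_invalid_config")
  if (sd_v <= 0 || sd_p <= 0 || sdlog < 0 || motor_sd < 0 || bias_sd < 0 ||
      k_dynamic < 0 || recalib_rate < 0 || side_offset_sd < 0)
    stop_delaymle("cohort_config values out of range", "delaymle_invalid_config")
  structure(vals, class = "cohort_config")
}

#' Draw a synthetic cohort
#'
#' Draws `n_subjects` sets of subject-level parameters from the population
#' model in `config`: per-subject visual and proprioceptive report variances
#' (log-normal), motor noise, constant sensory biases, recalibration rate, and
#' side offset. Integration weights are then filled in by
#' [set_mle_weights()]: static-task weights are the reliability (MLE) weights
#' implied by the subject's variances, and the dynamic-task weight is
#' `1 - k_dynamic * predicted_bimodal_variance` (clipped to `[0, 1]`).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame of class `"cohort"`, one row per subject, with columns
#'   `subject_id`, `sigma2_v`, `sigma2_p`, `motor_noise`, `bias_v`, `bias_p`,
#'   `w_static_v`, `w_static_p`, `w_dynamic`, `recalib_rate`, `side_offset`.
#' @examples
#' cohort <- make_cohort(24, seed = 1)
#' @export
make_cohort <- function(n_subjects, config = cohort_config(), seed = NULL) {
  if (!is_number(n_subjects) || n_subjects < 1)
    stop_delaymle("'n_subjects' must be >= 1", "delaymle_invalid_config")
  if (!inherits(config, "cohort_config"))
    stop_delaymle("'config' must be a cohort_config()", "delaymle_invalid_config")
  n <- as.integer(n_subjects)
  with_seed(seed, {
    cohort <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      sigma2_v = stats::rlnorm(n, log(config$sd_v^2), config$sdlog),
      sigma2_p = stats::rlnorm(n, log(config$sd_p^2), config$sdlog),
      motor_noise = rep(config$motor_sd^2, n),
      bias_v = stats::rnorm(n, 0, config$bias_sd),
      bias_p = stats::rnorm(n, 0, config$bias_sd),
      recalib_rate = rep(config$recalib_rate, n),
      side_offset = stats::rnorm(n, 0, config$side_offset_sd),
      stringsAsFactors = FALSE
    )
    cohort <- set_mle_weights(cohort, k = config$k_dynamic)
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Assign integration weights from subject variances
#'
#' Static-task weights follow the reliability (maximum-likelihood) rule: the
#' weight on the attended cue equals the other modality's variance over the
#' variance sum (`w_static_v = sigma2_p / (sigma2_v + sigma2_p)` when vision
#' is attended, and symmetrically for proprioception). The dynamic-task
#' weight on the attended cue is `clip(1 - k * var_bimodal, 0, 1)`, where
#' `var_bimodal` is the predicted bimodal variance: `k = 0` gives purely
#' unimodal dynamic reports, while `k > 0` makes subjects with larger bimodal
#' variance lean more on the ignored modality.
#'
#' @param cohort A cohort data.frame with `sigma2_v`, `sigma2_p` columns.
#' @param k Susceptibility coefficient (1/m^2, >= 0; default 0).
#' @return The cohort with `w_static_v`, `w_static_p`, `w_dynamic` columns
#'   set.
#' @export
set_mle_weights <- function(cohort, k = 0) {
  if (!is_number(k) || k < 0)
    stop_delaymle("'k' must be a single non-negative number",
                  "delaymle_invalid_config")
  s <- cohort$sigma2_v + cohort$sigma2_p
  cohort$w_static_v <- cohort$sigma2_p / s
  cohort$w_static_p <- cohort$sigma2_v / s
  vb <- cohort$sigma2_v * cohort$sigma2_p / s
  cohort$w_dynamic <- pmin(pmax(1 - k * vb, 0), 1)
  cohort
}
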