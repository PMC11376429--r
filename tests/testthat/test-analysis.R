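make_static_trials <- function(n_subjects, seed, config = cohort_config()) {
  cohort <- make_cohort(n_subjects, config, seed = seed)
  simulate_experiment(experiment_design("exp1_static"), cohort,
                      seed = seed + 1)
}

test_that("report errors are signed toward the other modality's cue", {
  # exp1 static geometry: V at 0.18, P at 0.12
  trials <- data.frame(
    subject_id = "S01", experiment = "exp1_static", task = "static",
    block = c(1L, 1L, 2L, 2L, 2L),
    trial_index = 1:5,
    trial_type = c("V", "P", "VP_V", "VP_P", "V"),
    attended = c("vision", "proprioception", "vision", "proprioception",
                 "vision"),
    cue_attended = c(0.18, 0.12, 0.18, 0.12, 0.18),
    cue_ignored = c(NA, NA, 0.12, 0.18, NA),
    report = c(0.18, 0.12, 0.15, 0.15, 0.17),
    peak_velocity = 0.3, stringsAsFactors = FALSE)
  err <- report_error(trials)$report_error
  expect_equal(err[1], 0)            # report at the attended cue
  expect_equal(err[2], 0)
  expect_equal(err[3], 0.03)         # VP_V shifted toward P
  expect_equal(err[4], 0.03)         # VP_P shifted toward V (mirrored sign)
  expect_equal(err[5], 0.01)         # unimodal: positive toward the P cue
  # missing report flagged, not dropped
  trials$report[3] <- NA
  flagged <- report_error(trials)
  expect_true(flagged$invalid[3])
  expect_true(is.na(flagged$report_error[3]))
  expect_error(report_error(trials[, -which(names(trials) == "report")]),
               class = "delaymle_schema_error")
})

test_that("baseline statistics recover the generative means and variances", {
  cohort <- make_cohort(1, seed = 20)
  cohort$sigma2_v <- 1e-4; cohort$sigma2_p <- 1e-4
  cohort$motor_noise <- 0
  cohort$bias_v <- 0.004; cohort$bias_p <- -0.006
  trials <- simulate_experiment(experiment_design("exp1_static"), cohort,
                                seed = 21)
  bs <- baseline_stats(trials)
  # 60 trials per modality: variance inside the chi-square 99% band
  band <- qchisq(c(0.005, 0.995), df = 59) / 59
  expect_gt(bs$var_v / 1e-4, band[1]); expect_lt(bs$var_v / 1e-4, band[2])
  expect_gt(bs$var_p / 1e-4, band[1]); expect_lt(bs$var_p / 1e-4, band[2])
  # means recover the constant biases within 3 SE. Errors are signed toward
  # the other modality: the V error flips sign (P lies at smaller y), the P
  # error keeps it (V lies at larger y).
  se <- sqrt(1e-4 / 60)
  expect_lt(abs(bs$mean_v - (-0.004)), 3 * se)
  expect_lt(abs(bs$mean_p - (-0.006)), 3 * se)
  # degenerate flag on constant reports
  const <- trials
  const$report <- const$cue_attended
  expect_true(baseline_stats(const)$degenerate)
  # fewer than 2 trials in a cell is an error
  thin <- trials[!(trials$trial_type == "V" & trials$block == 1 &
                     trials$trial_index > 2), ]
  thin <- thin[!(thin$trial_type == "V" & thin$block == 1), ]
  expect_error(baseline_stats(thin), class = "delaymle_undefined_variance")
})

test_that("predicted bimodal variance shares the combination algebra", {
  expect_equal(predicted_bimodal_variance(2e-4, 2e-4), 1e-4)
  expect_equal(predicted_bimodal_variance(1e-4, 4e-4), 0.8e-4)
  set.seed(22)
  va <- runif(20, 1e-6, 1e-3); vb <- runif(20, 1e-6, 1e-3)
  pv <- predicted_bimodal_variance(va, vb)
  expect_true(all(pv < pmin(va, vb)))
  expect_equal(pv, vapply(seq_along(va), function(i)
    mle_combine(gaussian_estimate(0, va[i]),
                gaussian_estimate(0, vb[i]))$variance, numeric(1)))
  expect_error(predicted_bimodal_variance(-1, 1),
               class = "delaymle_invalid_parameter")
})

test_that("biases vanish for w = 1 cohorts and reach 3 cm at equal-variance MLE", {
  # w = 1, noiseless: all biases zero
  quiet <- simulate_experiment(experiment_design("exp1_static"),
                               noiseless_cohort(3, w_static = 1), seed = 23)
  b0 <- compute_bias(quiet)
  expect_equal(b0$bias_vpv, rep(0, 3), tolerance = 1e-4)
  expect_equal(b0$bias_vpp, rep(0, 3), tolerance = 1e-4)
  # equal-variance MLE cohort: mean bias ~ (1 - 0.5) * 0.06 both conditions
  cohort <- make_cohort(12, seed = 24)
  cohort$sigma2_v <- cohort$sigma2_p <- 1e-4
  cohort <- set_mle_weights(cohort)
  trials <- simulate_experiment(experiment_design("exp1_static"), cohort,
                                seed = 25)
  b <- compute_bias(trials)
  se <- sd(b$bias_vpv) / sqrt(12)
  expect_lt(abs(mean(b$bias_vpv) - 0.03), 3 * se + 1e-3)
  expect_lt(abs(mean(b$bias_vpp) - 0.03), 3 * se + 1e-3)
  # baseline subtraction: adding a constant to all of a subject's reports
  # leaves biases unchanged
  shifted <- trials
  shifted$report <- shifted$report + 0.05
  expect_equal(compute_bias(shifted)$bias_vpv, b$bias_vpv, tolerance = 1e-12)
})

test_that("bias-variance regression detects the generative dependence", {
  b <- data.frame(subject_id = sprintf("S%02d", 1:6),
                  bias_vpv = rep(0.01, 6), bias_vpp = rep(0.01, 6),
                  max_bias = rep(0.01, 6),
                  pred_var_bimodal = seq(1e-5, 6e-5, by = 1e-5))
  # lm warns about the deliberately perfect fits of these fixtures
  flat <- suppressWarnings(bias_variance_regression(b))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  # perfectly collinear points: r^2 = 1
  b$max_bias <- 100 * b$pred_var_bimodal
  lin <- suppressWarnings(bias_variance_regression(b))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$slope, 100)
  b$pred_var_bimodal <- 1e-5
  expect_error(bias_variance_regression(b),
               class = "delaymle_invalid_parameter")
  # generative k > 0 dynamic cohort: positive slope
  cohort <- make_cohort(20, cohort_config(k_dynamic = 3000), seed = 26)
  trials <- simulate_experiment(experiment_design("exp1_dynamic"), cohort,
                                seed = 27)
  reg <- bias_variance_regression(compute_bias(trials))
  expect_gt(reg$slope, 0)
})

test_that("unimodal shifts are centred on zero without drift and positive with it", {
  trials <- make_static_trials(8, seed = 28)
  sh <- unimodal_shift(trials)
  se <- sd(c(sh$shift_v, sh$shift_p)) / sqrt(16)
  expect_lt(abs(mean(c(sh$shift_v, sh$shift_p))), 4 * se)
  drift <- make_static_trials(8, seed = 29,
                              config = cohort_config(recalib_rate = 1e-4))
  expect_gt(mean(unlist(unimodal_shift(drift)[c("shift_v", "shift_p")])), 0.003)
  # equal constant offsets to both blocks cancel in the shift
  shifted <- trials
  shifted$report <- shifted$report + 0.02
  expect_equal(unimodal_shift(shifted)$shift_v, sh$shift_v, tolerance = 1e-12)
  expect_error(unimodal_shift(trials[trials$block == 2, ]),
               class = "delaymle_missing_trials")
})

test_that("sign-flip test is exact for small n and sane at the extremes", {
  # all-zero biases: p = 1
  expect_equal(suppressWarnings(sign_flip_test(rep(0, 4)))$p_value, 1)
  # n = 5: package result equals brute-force enumeration over 2^5 patterns
  x <- c(0.031, -0.004, 0.018, 0.022, 0.009)
  got <- sign_flip_test(x, n_perm = 10000)
  expect_true(got$exact)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  brute <- mean(abs(signs %*% x / 5) >= abs(mean(x)) - 1e-15)
  expect_equal(got$p_value, brute)
  # strong effect: small p
  expect_lt(sign_flip_test(rep(0.03, 12) + rnorm(12, 0, 1e-3),
                           n_perm = 4000, seed = 1)$p_value, 0.01)
})

test_that("group inference separates an integrating static task from a unimodal dynamic task", {
  cohort <- make_cohort(10, seed = 30)
  st <- simulate_experiment(experiment_design("exp1_static"), cohort,
                            seed = 31)
  dy <- simulate_experiment(experiment_design("exp1_dynamic"), cohort,
                            seed = 32)
  gi <- group_inference(compute_bias(st), compute_bias(dy), n_perm = 2000,
                        seed = 33)
  expect_true(gi$interaction$paired)
  expect_lt(gi$interaction$p_value, 0.05)
  cond <- gi$conditions
  expect_lt(cond$p_value[cond$task == "static" & cond$condition == "VP_V"], 0.05)
  # CIs contain their point estimates
  expect_true(all(cond$ci_lower <= cond$mean_bias &
                    cond$mean_bias <= cond$ci_upper))
  # independent cohorts are flagged
  dy2 <- dy; dy2$subject_id <- paste0("X", dy2$subject_id)
  gi2 <- group_inference(compute_bias(st), compute_bias(dy2), n_perm = 500,
                         seed = 34)
  expect_false(gi2$interaction$paired)
})

test_that("estimated weights recover the generative weights across subjects", {
  cohort <- make_cohort(20, seed = 35)
  trials <- simulate_experiment(experiment_design("exp1_static"), cohort,
                                seed = 36)
  fit <- bias_fit(trials, n_perm = 200, seed = 37)
  rmse <- sqrt(mean((fit$bias$w_hat_v - cohort$w_static_v)^2 +
                      (fit$bias$w_hat_p - cohort$w_static_p)^2) / 2)
  expect_lt(rmse, 0.05)
})

test_that("the bias estimator is unbiased over repeated cohorts", {
  # 60 small cohorts: mean estimated bias matches (1 - w) * 0.06
  set.seed(38)
  errs <- replicate(60, {
    cohort <- make_cohort(2)
    trials <- simulate_experiment(experiment_design("exp1_static"), cohort)
    b <- compute_bias(trials)
    truth <- (1 - cohort$w_static_v) * 0.06
    b$bias_vpv - truth
  })
  mc_se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * mc_se)
})
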