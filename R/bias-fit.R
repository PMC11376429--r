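#' Fit the integration-bias model to a trial table
#'
#' The package's central fitting function. From a trial table (simulated or
#' read from CSV) it computes signed report errors, per-subject baseline
#' statistics, the per-subject bias table, sign-flip permutation tests of the
#' two condition biases against zero, the estimated integration weights
#' `w_hat = 1 - bias / offset` (with `offset` the 6 cm cue separation), the
#' unimodal block-2-minus-block-1 shift, and the regression of maximal bias
#' on predicted bimodal variance.
#'
#' @param trials A trial table (one task / experiment).
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed Optional integer seed for the permutation tests.
#' @param velocity_adjust If `TRUE`, report errors are linearly adjusted for
#'   peak report velocity (pooled OLS slope, centred) before bias
#'   computation; off by default for synthetic data.
#' @param offset Cue separation along the discrepancy axis in metres
#'   (default 0.06), used to convert biases into integration weights.
#' @return An object of class `"bias_fit"` with components `bias` (the
#'   [compute_bias()] table, plus `w_hat_v`, `w_hat_p`), `baseline`,
#'   `tests` (per-condition sign-flip tests), `shift` ([unimodal_shift()],
#'   when both blocks contain unimodal trials), `regression`
#'   ([bias_variance_regression()], when >= 3 subjects), `task`,
#'   `experiment`, `n_subjects`, and `call`. Methods: [print.bias_fit()],
#'   [summary.bias_fit()], [coef.bias_fit()], [plot.bias_fit()].
#' @examples
#' cohort <- make_cohort(8, seed = 1)
#' trials <- simulate_experiment(experiment_design("exp1_static"), cohort,
#'                               seed = 2)
#' fit <- bias_fit(trials, n_perm = 1000, seed = 3)
#' coef(fit)
#' @export
bias_fit <- function(trials, n_perm = 10000L, seed = NULL,
                     velocity_adjust = FALSE, offset = 0.06) {
  trials <- report_error(trials)
  if (velocity_adjust && "peak_velocity" %in% names(trials)) {
    ok <- !trials$invalid
    b <- stats::coef(stats::lm(report_error ~ peak_velocity,
                               data = trials[ok, ]))[["peak_velocity"]]
    trials$report_error[ok] <- trials$report_error[ok] -
      b * (trials$peak_velocity[ok] - mean(trials$peak_velocity[ok]))
  }
  bias <- compute_bias(trials)
  bias$w_hat_v <- 1 - bias$bias_vpv / offset
  bias$w_hat_p <- 1 - bias$bias_vpp / offset
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  tests <- list(
    VP_V = sign_flip_test(bias$bias_vpv, n_perm = n_perm, seed = seeds[[1L]]),
    VP_P = sign_flip_test(bias$bias_vpp, n_perm = n_perm, seed = seeds[[2L]])
  )
  shift <- tryCatch(unimodal_shift(trials), delaymle_missing_trials = function(e) NULL)
  regression <- if (nrow(bias) >= 3L &&
                    stats::var(bias$pred_var_bimodal) > 0)
    bias_variance_regression(bias)
  else NULL
  structure(list(bias = bias, baseline = baseline_stats(trials),
                 tests = tests, shift = shift, regression = regression,
                 task = trials$task[1L], experiment = trials$experiment[1L],
                 n_subjects = nrow(bias), n_perm = n_perm, seed = seed,
                 offset = offset, velocity_adjust = velocity_adjust,
                 call = match.call()),
            class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf("Integration-bias fit: %s (%s task), %d subjects\n",
              x$experiment, x$task, x$n_subjects))
  for (cond in c("VP_V", "VP_P")) {
    tst <- x$tests[[cond]]
    cat(sprintf("  %s bias: %+0.4f m (p = %.4g, sign-flip, %s)\n", cond,
                tst$statistic, tst$p_value,
                if (tst$exact) "exact" else sprintf("%d perms", x$n_perm)))
  }
  if (!is.null(x$regression))
    cat(sprintf("  max bias ~ predicted bimodal variance: slope %.3g, r^2 %.3f, p = %.4g\n",
                x$regression$slope, x$regression$r_squared,
                x$regression$p_value))
  invisible(x)
}

#' Extract fitted group-level coefficients
#'
#' @param object A [bias_fit()].
#' @param ... Unused.
#' @return Named vector: group mean biases (m), mean estimated integration
#'   weights per condition, and (if computed) the bias-on-variance slope.
#' @export
coef.bias_fit <- function(object, ...) {
  out <- c(bias_vpv = mean(object$bias$bias_vpv),
           bias_vpp = mean(object$bias$bias_vpp),
           w_hat_v = mean(object$bias$w_hat_v),
           w_hat_p = mean(object$bias$w_hat_p))
  if (!is.null(object$regression))
    out <- c(out, slope_bias_variance = object$regression$slope)
  out
}

#' Summarise an integration-bias fit
#'
#' @param object A [bias_fit()].
#' @param ... Unused.
#' @return An object of class `"summary.bias_fit"` printing the per-condition
#'   group biases with confidence intervals and permutation p-values, the
#'   estimated integration weights, the unimodal recalibration shift, and the
#'   bias-variance regression (with and without the largest-residual
#'   subject).
#' @export
summary.bias_fit <- function(object, ...) {
  b <- object$bias
  ci <- function(x) mean(x) + stats::qt(c(0.025, 0.975), length(x) - 1L) *
    stats::sd(x) / sqrt(length(x))
  rows <- lapply(c(VP_V = "bias_vpv", VP_P = "bias_vpp"), function(col) {
    x <- b[[col]]
    c(mean = mean(x), ci(x))
  })
  structure(list(fit = object, rows = rows), class = "summary.bias_fit")
}

#' @export
print.summary.bias_fit <- function(x, ...) {
  obj <- x$fit
  cat(sprintf("Integration-bias fit: %s (%s task), %d subjects, %d permutations\n",
              obj$experiment, obj$task, obj$n_subjects, obj$n_perm))
  cat(sprintf("Cue separation: %.3f m; velocity adjustment: %s\n\n",
              obj$offset, if (obj$velocity_adjust) "on" else "off"))
  for (cond in names(x$rows)) {
    r <- x$rows[[cond]]
    tst <- obj$tests[[cond]]
    cat(sprintf("  %s: mean bias %+0.4f m, 95%% CI [%+0.4f, %+0.4f], p = %.4g\n",
                cond, r[1L], r[2L], r[3L], tst$p_value))
  }
  cat(sprintf("\n  mean estimated weights: w_hat_v = %.3f, w_hat_p = %.3f\n",
              mean(obj$bias$w_hat_v), mean(obj$bias$w_hat_p)))
  if (!is.null(obj$shift))
    cat(sprintf("  unimodal block shift: V %+0.4f m, P %+0.4f m (mean)\n",
                mean(obj$shift$shift_v), mean(obj$shift$shift_p)))
  if (!is.null(obj$regression)) {
    r <- obj$regression
    cat(sprintf("  max bias ~ predicted bimodal variance: slope %.3g (r^2 %.3f, p %.4g)\n",
                r$slope, r$r_squared, r$p_value))
    cat(sprintf("    without largest residual (%s): slope %.3g (r^2 %.3f, p %.4g)\n",
                r$dropped_subject, r$slope_trimmed, r$r_squared_trimmed,
                r$p_value_trimmed))
  }
  invisible(x)
}

#' Plot an integration-bias fit
#'
#' Two base-graphics panels: per-subject condition biases (with group means)
#' and the scatter of maximal bias against predicted bimodal variance with
#' the OLS line.
#'
#' @param x A [bias_fit()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bias_fit <- function(x, ...) {
  b <- x$bias
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2.5, 1))
  on.exit(graphics::par(op))
  graphics::stripchart(list(VP_V = b$bias_vpv, VP_P = b$bias_vpp),
                       vertical = TRUE, method = "jitter", pch = 16,
                       col = "grey40", ylab = "bias toward ignored cue (m)",
                       main = sprintf("%s (%s task)", x$experiment, x$task))
  graphics::abline(h = 0, lty = 2)
  graphics::points(1:2, c(mean(b$bias_vpv), mean(b$bias_vpp)), pch = 3,
                   cex = 2, lwd = 2, col = "red")
  graphics::plot(b$pred_var_bimodal, b$max_bias,
                 xlab = "predicted bimodal variance (m^2)",
                 ylab = "max bias (m)", pch = 16, ...)
  if (!is.null(x$regression))
    graphics::abline(stats::lm(max_bias ~ pred_var_bimodal, data = b))
  invisible(x)
}
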