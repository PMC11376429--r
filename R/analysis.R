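#' Signed report errors on the discrepancy axis
#'
#' Adds a `report_error` column: the signed difference between the reported
#' and the attended-cue position, oriented so that positive errors point
#' toward the other modality's cue. For bimodal trials the reference is the
#' trial's ignored cue; for unimodal trials it is the other modality's
#' standard cue location for that subject (recovered from the subject's own
#' unimodal trials, which makes the convention robust to counterbalancing).
#'
#' @param trials A trial table (see [simulate_experiment()] /
#'   [read_trial_table()]).
#' @return The trial table with a `report_error` column (metres). Rows with a
#'   missing report get `NA` and are flagged in a logical `invalid` column.
#' @export
report_error <- function(trials) {
  required <- c("subject_id", "trial_type", "attended", "cue_attended",
                "cue_ignored", "report", "block")
  miss <- setdiff(required, names(trials))
  if (length(miss))
    stop_delaymle(paste("trial table lacks column(s):",
                        paste(miss, collapse = ", ")),
                  "delaymle_schema_error")
  # canonical cue per subject x modality, from that subject's unimodal trials
  uni <- trials$trial_type %in% c("V", "P")
  key <- function(id, mod) paste(id, mod, sep = "\r")
  canon <- tapply(trials$cue_attended[uni],
                  key(trials$subject_id[uni], trials$attended[uni]),
                  function(x) x[1L])
  other <- ifelse(trials$attended == "vision", "proprioception", "vision")
  reference <- ifelse(uni,
                      as.numeric(canon[key(trials$subject_id, other)]),
                      trials$cue_ignored)
  err <- (trials$report - trials$cue_attended) *
    sign(reference - trials$cue_attended)
  trials$invalid <- !is.finite(trials$report)
  err[trials$invalid] <- NA_real_
  trials$report_error <- err
  trials
}

#' Baseline unimodal statistics per subject
#'
#' Sample mean and unbiased variance of block-1 unimodal report errors, per
#' subject and modality. These baselines anchor the bias computation and feed
#' the predicted bimodal variance.
#'
#' @param trials A trial table (a `report_error` column is added if absent).
#' @return A data.frame with one row per subject: `mean_v`, `mean_p`,
#'   `var_v`, `var_p`, trial counts, and a `degenerate` flag for zero
#'   variance.
#' @export
baseline_stats <- function(trials) {
  if (!"report_error" %in% names(trials)) trials <- report_error(trials)
  b1 <- trials[trials$block == 1L & trials$trial_type %in% c("V", "P") &
                 !trials$invalid, ]
  subjects <- unique(trials$subject_id)
  stat_cell <- function(x, what) {
    if (length(x) < 2L)
      stop_delaymle("fewer than 2 baseline trials in a subject/modality cell; variance undefined",
                    "delaymle_undefined_variance")
    if (what == "mean") mean(x) else stats::var(x)
  }
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (mod in c("V", "P")) {
    errs <- lapply(subjects, function(s)
      b1$report_error[b1$subject_id == s & b1$trial_type == mod])
    out[[paste0("mean_", tolower(mod))]] <-
      vapply(errs, stat_cell, numeric(1L), what = "mean")
    out[[paste0("var_", tolower(mod))]] <-
      vapply(errs, stat_cell, numeric(1L), what = "var")
    out[[paste0("n_", tolower(mod))]] <- lengths(errs)
  }
  out$degenerate <- out$var_v == 0 | out$var_p == 0
  out
}

#' Predicted bimodal variance
#'
#' The variance of the ideal reliability-weighted bimodal estimate,
#' `var_v * var_p / (var_v + var_p)` — the same formula as
#' [mle_combine()]'s combined variance. Always smaller than either input.
#'
#' @param var_v,var_p Unimodal variances in m^2 (vectorised, > 0).
#' @return Predicted bimodal variance in m^2.
#' @export
predicted_bimodal_variance <- function(var_v, var_p) {
  if (any(!is.finite(var_v)) || any(!is.finite(var_p)) ||
      any(var_v <= 0) || any(var_p <= 0))
    stop_delaymle("variances must be positive and finite",
                  "delaymle_invalid_parameter")
  # single implementation shared with mle_combine (identical algebra)
  mapply(function(a, b) mle_combine(gaussian_estimate(0, a),
                                    gaussian_estimate(0, b))$variance,
         var_v, var_p)
}

#' Per-subject integration biases
#'
#' The bias on each bimodal condition is the mean bimodal report error minus
#' the mean baseline (block 1) report error of the attended modality
#' (e.g. VP_V minus baseline V). Positive biases point toward the ignored
#' modality's cue — the signature of residual multisensory integration.
#' `max_bias` is the larger of the two condition biases regardless of
#' modality, and `pred_var_bimodal` is the predicted bimodal variance from
#' the subject's baseline variances.
#'
#' @param trials A trial table.
#' @return A data.frame of class `"bias_table"`, one row per subject, with
#'   columns `bias_vpv`, `bias_vpp`, `max_bias`, the baseline means and
#'   variances, and `pred_var_bimodal`.
#' @export
compute_bias <- function(trials) {
  if (!"report_error" %in% names(trials)) trials <- report_error(trials)
  base <- baseline_stats(trials)
  bim <- trials[trials$trial_type %in% c("VP_V", "VP_P") & !trials$invalid, ]
  if (nrow(bim) == 0L)
    stop_delaymle("no bimodal trials in the table", "delaymle_missing_trials")
  mean_cell <- function(s, tt) {
    x <- bim$report_error[bim$subject_id == s & bim$trial_type == tt]
    if (length(x) == 0L)
      stop_delaymle(sprintf("subject %s has no %s trials", s, tt),
                    "delaymle_missing_trials")
    mean(x)
  }
  base$bias_vpv <- vapply(base$subject_id, mean_cell, numeric(1L), tt = "VP_V") -
    base$mean_v
  base$bias_vpp <- vapply(base$subject_id, mean_cell, numeric(1L), tt = "VP_P") -
    base$mean_p
  base$max_bias <- pmax(base$bias_vpv, base$bias_vpp)
  base$pred_var_bimodal <- predicted_bimodal_variance(base$var_v, base$var_p)
  class(base) <- c("bias_table", "data.frame")
  base
}

#' Regression of maximal bias on predicted bimodal variance
#'
#' Ordinary least squares of each subject's largest bimodal bias on their
#' predicted bimodal variance — the individual-differences test of the delay
#' model: in a dynamic task, subjects with wider bimodal estimates should be
#' more susceptible to the ignored modality. Reported with and without the
#' single largest-residual subject, since one outlying participant can carry
#' or mask such a correlation at typical sample sizes.
#'
#' @param bias_table A [compute_bias()] table (>= 3 subjects).
#' @return A list with `slope`, `r_squared`, `p_value` (two-sided, slope),
#'   `n`, and the same quantities with the largest-|residual| subject removed
#'   (`slope_trimmed`, `r_squared_trimmed`, `p_value_trimmed`,
#'   `dropped_subject`).
#' @export
bias_variance_regression <- function(bias_table) {
  if (nrow(bias_table) < 3L)
    stop_delaymle("need at least 3 subjects for the regression",
                  "delaymle_invalid_parameter")
  if (stats::var(bias_table$pred_var_bimodal) == 0)
    stop_delaymle("predictor (predicted bimodal variance) has zero variance",
                  "delaymle_invalid_parameter")
  fit <- stats::lm(max_bias ~ pred_var_bimodal, data = bias_table)
  pull <- function(f) {
    s <- summary(f)
    co <- stats::coef(s)
    list(slope = co["pred_var_bimodal", "Estimate"],
         r_squared = s$r.squared,
         p_value = co["pred_var_bimodal", "Pr(>|t|)"])
  }
  full <- pull(fit)
  drop_i <- which.max(abs(stats::residuals(fit)))
  trimmed <- bias_table[-drop_i, , drop = FALSE]
  tr <- if (nrow(trimmed) >= 3L && stats::var(trimmed$pred_var_bimodal) > 0)
    pull(stats::lm(max_bias ~ pred_var_bimodal, data = trimmed))
  else list(slope = NA_real_, r_squared = NA_real_, p_value = NA_real_)
  c(full,
    list(n = nrow(bias_table),
         slope_trimmed = tr$slope, r_squared_trimmed = tr$r_squared,
         p_value_trimmed = tr$p_value,
         dropped_subject = bias_table$subject_id[drop_i]))
}

#' Unimodal report-error shift between blocks
#'
#' Per subject and modality, the mean unimodal report error in the mixed
#' block minus the baseline block. A positive shift (toward the other
#' modality) on unimodal trials after exposure to bimodal conflict is the
#' signature of sensory recalibration.
#'
#' @param trials A trial table with unimodal trials in both blocks.
#' @return A data.frame with one row per subject: `shift_v`, `shift_p`
#'   (metres).
#' @export
unimodal_shift <- function(trials) {
  if (!"report_error" %in% names(trials)) trials <- report_error(trials)
  uni <- trials[trials$trial_type %in% c("V", "P") & !trials$invalid, ]
  subjects <- unique(trials$subject_id)
  shift_cell <- function(s, tt) {
    b1 <- uni$report_error[uni$subject_id == s & uni$trial_type == tt &
                             uni$block == 1L]
    b2 <- uni$report_error[uni$subject_id == s & uni$trial_type == tt &
                             uni$block == 2L]
    if (length(b1) == 0L || length(b2) == 0L)
      stop_delaymle(sprintf("subject %s lacks unimodal %s trials in one block",
                            s, tt),
                    "delaymle_missing_trials")
    mean(b2) - mean(b1)
  }
  data.frame(subject_id = subjects,
             shift_v = vapply(subjects, shift_cell, numeric(1L), tt = "V"),
             shift_p = vapply(subjects, shift_cell, numeric(1L), tt = "P"),
             stringsAsFactors = FALSE)
}

#' One-sample sign-flip permutation test
#'
#' Tests whether the mean of `x` differs from zero by randomly flipping the
#' sign of each observation — exact under the null hypothesis of a
#' distribution symmetric about zero, with no distributional assumptions
#' otherwise. When the full set of `2^n` sign patterns is no larger than
#' `n_perm`, the test enumerates them exactly; otherwise it draws `n_perm`
#' random sign patterns and reports the add-one Monte-Carlo p-value
#' `(1 + #{|T*| >= |T|}) / (n_perm + 1)`. With fewer than 5 observations the
#' exact enumeration is used with a warning (the attainable p-values are very
#' coarse).
#'
#' @param x Numeric vector of per-subject statistics.
#' @param n_perm Number of random sign patterns (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo branch.
#' @param alternative `"two.sided"` (default) or `"greater"` (mean > 0).
#' @return A list with `statistic` (the observed mean), `p_value`, `n`,
#'   `exact`, and `alternative`.
#' @export
sign_flip_test <- function(x, n_perm = 10000L, seed = NULL,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L)
    stop_delaymle("no finite observations", "delaymle_invalid_parameter")
  if (n < 5L)
    warning("fewer than 5 observations: exact enumeration over 2^n sign patterns; p-values are coarse")
  obs <- mean(x)
  tol <- 1e-12 * max(1, abs(obs))
  as_extreme <- function(perm) {
    if (alternative == "two.sided") abs(perm) >= abs(obs) - tol
    else perm >= obs - tol
  }
  if (n < 5L || 2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.numeric(signs %*% x) / n
    p <- mean(as_extreme(perm))
    exact <- TRUE
  } else {
    p <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      perm <- as.numeric(signs %*% x) / n
      (1 + sum(as_extreme(perm))) / (n_perm + 1)
    })
    exact <- FALSE
  }
  list(statistic = obs, p_value = p, n = n, exact = exact,
       alternative = alternative)
}

#' Group-level inference across the static and dynamic tasks
#'
#' Summarises and tests the condition biases of a static and a dynamic
#' cohort: per task and condition, the group mean bias with a t-based 95%
#' confidence interval and a one-sample sign-flip permutation p-value
#' (two-sided, against zero bias); and the task-by-condition contrast,
#' tested by sign-flipping each subject's static-minus-dynamic mean bias
#' (paired, when the two tables share subject ids) or by label permutation
#' of the subject means (independent cohorts, flagged). Two planned
#' contrasts per task; no multiplicity correction is applied, which the
#' printout states.
#'
#' @param static_bias,dynamic_bias [compute_bias()] tables (or `bias_fit`
#'   objects) for the static and dynamic tasks.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `"group_inference"`: a list with a `conditions`
#'   data.frame (task, condition, mean, CI, p), an `interaction` list
#'   (estimate, p, paired flag), `n_perm`, and `seed`.
#' @export
group_inference <- function(static_bias, dynamic_bias, n_perm = 10000L,
                            seed = NULL) {
  get_table <- function(x)
    if (inherits(x, "bias_fit")) x$bias else x
  st <- get_table(static_bias); dy <- get_table(dynamic_bias)
  seeds <- if (is.null(seed)) vector("list", 6L)
           else as.list(seed + 0:5)
  cond_row <- function(tab, task, col, cond, sd_seed) {
    x <- tab[[col]]
    ci <- mean(x) + stats::qt(c(0.025, 0.975), df = length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
    tst <- sign_flip_test(x, n_perm = n_perm, seed = sd_seed)
    data.frame(task = task, condition = cond, n = length(x),
               mean_bias = mean(x), ci_lower = ci[1L], ci_upper = ci[2L],
               p_value = tst$p_value, exact = tst$exact,
               stringsAsFactors = FALSE)
  }
  conditions <- rbind(
    cond_row(st, "static", "bias_vpv", "VP_V", seeds[[1L]]),
    cond_row(st, "static", "bias_vpp", "VP_P", seeds[[2L]]),
    cond_row(dy, "dynamic", "bias_vpv", "VP_V", seeds[[3L]]),
    cond_row(dy, "dynamic", "bias_vpp", "VP_P", seeds[[4L]])
  )
  st_mean <- (st$bias_vpv + st$bias_vpp) / 2
  dy_mean <- (dy$bias_vpv + dy$bias_vpp) / 2
  paired <- setequal(st$subject_id, dy$subject_id) &&
    !anyDuplicated(st$subject_id)
  if (paired) {
    d <- st_mean[match(dy$subject_id, st$subject_id)] - dy_mean
    tst <- sign_flip_test(d, n_perm = n_perm, seed = seeds[[5L]])
    interaction <- list(estimate = mean(d), p_value = tst$p_value,
                        paired = TRUE, exact = tst$exact)
  } else {
    obs <- mean(st_mean) - mean(dy_mean)
    pool <- c(st_mean, dy_mean)
    n1 <- length(st_mean)
    p <- with_seed(seeds[[6L]], {
      perm <- replicate(n_perm, {
        idx <- sample.int(length(pool), n1)
        mean(pool[idx]) - mean(pool[-idx])
      })
      (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    })
    interaction <- list(estimate = obs, p_value = p, paired = FALSE,
                        exact = FALSE)
  }
  structure(list(conditions = conditions, interaction = interaction,
                 n_perm = n_perm, seed = seed),
            class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  cat("Group-level bias inference (sign-flip permutation tests)\n")
  cat(sprintf("  %d permutations; %s interaction test\n", x$n_perm,
              if (x$interaction$paired) "paired (matched subjects)"
              else "independent-cohorts"))
  df <- x$conditions
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-7s %-5s n=%2d  mean bias %+0.4f m  95%% CI [%+0.4f, %+0.4f]  p = %.4g\n",
                df$task[i], df$condition[i], df$n[i], df$mean_bias[i],
                df$ci_lower[i], df$ci_upper[i], df$p_value[i]))
  cat(sprintf("  task x condition contrast: %+0.4f m, p = %.4g\n",
              x$interaction$estimate, x$interaction$p_value))
  cat("  (two planned contrasts per task; no multiple-comparison correction)\n")
  invisible(x)
}
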