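#' Experiment designs for the conflict tasks
#'
#' Encodes the four task designs: trial-type composition of the baseline and
#' mixed blocks, the axis along which the visual and proprioceptive cues
#' disagree, and the cue geometry for each counterbalancing side. In every
#' design the two cues are 6 cm apart along the discrepancy axis.
#'
#' * `exp1_static` — static estimation: visual target 18 cm and proprioceptive
#'   endpoint 12 cm ahead of the start (discrepancy along y). Baseline block
#'   of 120 unimodal trials (60 V + 60 P); mixed block of 24 V, 24 P, 60 VP_V,
#'   60 VP_P.
#' * `exp1_dynamic` — dynamic estimation: opposing arcs with midpoints 3 cm
#'   left/right of the midline (discrepancy along x); modality-side pairing
#'   counterbalanced. Baseline block of 60 unimodal trials; mixed block of
#'   20 V, 20 P, 60 VP_V, 60 VP_P.
#' * `exp2` — static estimation with laterally displaced targets (3 cm left
#'   and right at 15 cm forward; discrepancy along x); blocks as
#'   `exp1_static`.
#' * `exp3` — dynamic estimation with same-side arcs, midpoints 3 cm (close)
#'   and 9 cm (far) right of the midline; blocks as `exp1_dynamic`.
#'
#' @param experiment One of `"exp1_static"`, `"exp1_dynamic"`, `"exp2"`,
#'   `"exp3"`.
#' @return A list of class `"experiment_design"` with elements `experiment`,
#'   `task`, `axis`, `block1`, `block2`, and `cues(side)` returning the
#'   named cue positions `c(vision = , proprioception = )` in metres for
#'   counterbalancing side `"A"` or `"B"`.
#' @export
experiment_design <- function(experiment = c("exp1_static", "exp1_dynamic",
                                             "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  static_blocks <- list(block1 = c(V = 60L, P = 60L),
                        block2 = c(V = 24L, P = 24L, VP_V = 60L, VP_P = 60L))
  dynamic_blocks <- list(block1 = c(V = 30L, P = 30L),
                         block2 = c(V = 20L, P = 20L, VP_V = 60L, VP_P = 60L))
  d <- switch(experiment,
    exp1_static = c(list(task = "static", axis = "y",
      cues = function(side) c(vision = 0.18, proprioception = 0.12)),
      static_blocks),
    exp1_dynamic = c(list(task = "dynamic", axis = "x",
      cues = function(side) {
        if (side == "A") c(vision = -0.03, proprioception = 0.03)
        else c(vision = 0.03, proprioception = -0.03)
      }), dynamic_blocks),
    exp2 = c(list(task = "static", axis = "x",
      cues = function(side) {
        if (side == "A") c(vision = -0.03, proprioception = 0.03)
        else c(vision = 0.03, proprioception = -0.03)
      }), static_blocks),
    exp3 = c(list(task = "dynamic", axis = "x",
      cues = function(side) {
        if (side == "A") c(vision = 0.03, proprioception = 0.09)
        else c(vision = 0.09, proprioception = 0.03)
      }), dynamic_blocks)
  )
  d$experiment <- experiment
  structure(d, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s (%s task, discrepancy along %s)\n",
              x$experiment, x$task, x$axis))
  cat("  block 1:", paste(names(x$block1), x$block1, collapse = ", "), "\n")
  cat("  block 2:", paste(names(x$block2), x$block2, collapse = ", "), "\n")
  invisible(x)
}

# Report model shared by simulate_trial and simulate_experiment.
# Returns mean and sd of the report on the discrepancy axis.
# drift: signed recalibration displacement already oriented toward the other
# modality's cue (applied to unimodal reports only).
report_model <- function(subject, task, trial_type, cue_v, cue_p, drift = 0) {
  switch(trial_type,
    V = list(attended = "vision", cue_attended = cue_v, cue_ignored = NA_real_,
             mean = cue_v + subject$bias_v + drift * sign(cue_p - cue_v),
             sd = sqrt(subject$sigma2_v + subject$motor_noise)),
    P = list(attended = "proprioception", cue_attended = cue_p,
             cue_ignored = NA_real_,
             mean = cue_p + subject$bias_p + drift * sign(cue_v - cue_p),
             sd = sqrt(subject$sigma2_p + subject$motor_noise)),
    VP_V = {
      w <- if (task == "static") subject$w_static_v else subject$w_dynamic
      list(attended = "vision", cue_attended = cue_v, cue_ignored = cue_p,
           mean = w * cue_v + (1 - w) * cue_p + subject$bias_v,
           sd = sqrt(w^2 * subject$sigma2_v + (1 - w)^2 * subject$sigma2_p +
                       subject$motor_noise))
    },
    VP_P = {
      w <- if (task == "static") subject$w_static_p else subject$w_dynamic
      list(attended = "proprioception", cue_attended = cue_p,
           cue_ignored = cue_v,
           mean = w * cue_p + (1 - w) * cue_v + subject$bias_p,
           sd = sqrt(w^2 * subject$sigma2_p + (1 - w)^2 * subject$sigma2_v +
                       subject$motor_noise))
    },
    stop_delaymle(sprintf("unknown trial type '%s'", trial_type),
                  "delaymle_invalid_trial_type")
  )
}

#' Simulate a single trial
#'
#' Draws one report from the subject's generative model. Unimodal reports are
#' `cue + bias + drift + noise` with noise variance `sigma2 + motor_noise`;
#' bimodal reports are the weighted combination `w * cue_attended + (1 - w) *
#' cue_ignored + bias + noise`, with `w` the subject's static (MLE) or dynamic
#' weight depending on the task, and noise variance `w^2 * sigma2_att +
#' (1 - w)^2 * sigma2_ign + motor_noise`. The expected signed bias toward the
#' ignored cue is therefore `(1 - w) * 0.06` m.
#'
#' @param subject A single-row cohort data.frame (see [make_cohort()]).
#' @param design An [experiment_design()].
#' @param trial_type One of `"V"`, `"P"`, `"VP_V"`, `"VP_P"`.
#' @param block Block number (1 or 2).
#' @param side Counterbalancing side, `"A"` or `"B"`.
#' @param drift Signed recalibration displacement (m) applied toward the
#'   other modality on unimodal trials (default 0).
#' @return A one-row data.frame in trial-table format.
#' @export
simulate_trial <- function(subject, design, trial_type, block, side = "A",
                           drift = 0) {
  stopifnot(inherits(design, "experiment_design"))
  if (!trial_type %in% c("V", "P", "VP_V", "VP_P"))
    stop_delaymle(sprintf("unknown trial type '%s'", trial_type),
                  "delaymle_invalid_trial_type")
  if (block == 1L && trial_type %in% c("VP_V", "VP_P"))
    stop_delaymle("bimodal trials do not occur in block 1",
                  "delaymle_invalid_trial_type")
  cues <- design$cues(side)
  m <- report_model(subject, design$task, trial_type,
                    cues[["vision"]], cues[["proprioception"]], drift)
  report <- stats::rnorm(1L, m$mean, m$sd)
  if (design$experiment == "exp2")
    report <- report + subject$side_offset * sign(m$cue_attended)
  data.frame(subject_id = subject$subject_id,
             experiment = design$experiment,
             task = design$task,
             block = as.integer(block),
             trial_index = NA_integer_,
             trial_type = trial_type,
             attended = m$attended,
             cue_attended = m$cue_attended,
             cue_ignored = m$cue_ignored,
             report = report,
             peak_velocity = pmax(0.05, stats::rnorm(1L, 0.35, 0.05)),
             stringsAsFactors = FALSE)
}

#' Simulate a full experiment for a cohort
#'
#' Produces the complete randomised trial table for every subject: the
#' baseline block of unimodal trials followed by the mixed block, with
#' trial-type order shuffled within block and the modality-side pairing
#' alternated across subjects (odd subjects side `"A"`, even side `"B"`).
#' When `recalib_rate > 0` and the task is static, unimodal reports in the
#' mixed block drift linearly toward the other modality's cue at
#' `recalib_rate` metres per mixed-block trial, emulating gradual sensory
#' recalibration under conflict.
#'
#' @param design An [experiment_design()].
#' @param cohort A cohort data.frame from [make_cohort()].
#' @param seed Optional integer seed; same seed, same table.
#' @return A data.frame (trial table), one row per trial, with columns
#'   `subject_id`, `experiment`, `task`, `block`, `trial_index`,
#'   `trial_type`, `attended`, `cue_attended`, `cue_ignored`, `report`,
#'   `peak_velocity`.
#' @examples
#' design <- experiment_design("exp1_static")
#' trials <- simulate_experiment(design, make_cohort(4, seed = 1), seed = 2)
#' @export
simulate_experiment <- function(design, cohort, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"), is.data.frame(cohort))
  with_seed(seed, {
    out <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      subject <- cohort[i, , drop = FALSE]
      side <- if (i %% 2L == 1L) "A" else "B"
      cues <- design$cues(side)
      types <- c(sample(rep(names(design$block1), design$block1)),
                 sample(rep(names(design$block2), design$block2)))
      n1 <- sum(design$block1)
      n <- length(types)
      block <- rep(c(1L, 2L), c(n1, n - n1))
      # recalibration drift index: position within the mixed block
      drift <- numeric(n)
      if (design$task == "static" && subject$recalib_rate > 0) {
        j <- pmax(seq_len(n) - n1, 0L)
        uni <- types %in% c("V", "P") & block == 2L
        drift[uni] <- subject$recalib_rate * j[uni]
      }
      mean_ <- numeric(n); sd_ <- numeric(n)
      attended <- character(n); cue_att <- numeric(n); cue_ign <- rep(NA_real_, n)
      for (tt in unique(types)) {
        sel <- types == tt
        m <- report_model(subject, design$task, tt,
                          cues[["vision"]], cues[["proprioception"]])
        attended[sel] <- m$attended
        cue_att[sel] <- m$cue_attended
        cue_ign[sel] <- m$cue_ignored
        mean_[sel] <- m$mean
        sd_[sel] <- m$sd
      }
      # re-apply drift (orientation toward the other modality's cue)
      dir <- ifelse(types == "V", sign(cues[["proprioception"]] - cues[["vision"]]),
                    ifelse(types == "P", sign(cues[["vision"]] - cues[["proprioception"]]), 0))
      mean_ <- mean_ + drift * dir
      report <- stats::rnorm(n, mean_, sd_)
      if (design$experiment == "exp2")
        report <- report + subject$side_offset * sign(cue_att)
      out[[i]] <- data.frame(subject_id = subject$subject_id,
                             experiment = design$experiment,
                             task = design$task,
                             block = block,
                             trial_index = seq_len(n),
                             trial_type = types,
                             attended = attended,
                             cue_attended = cue_att,
                             cue_ignored = cue_ign,
                             report = report,
                             peak_velocity = pmax(0.05, stats::rnorm(n, 0.35, 0.05)),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
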