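trial_table_columns <- c("subject_id", "experiment", "task", "block",
                         "trial_index", "trial_type", "attended",
                         "cue_attended", "cue_ignored", "report",
                         "peak_velocity")

#' Read a trial table from CSV
#'
#' Reads a comma-separated trial table (UTF-8, '.' decimal, header row
#' required) and validates its schema. Malformed rows — non-finite report,
#' unknown trial type or block — are not silently dropped: they are removed
#' from the returned table and attached as the `"rejects"` attribute.
#'
#' @param path Path to a CSV file with the trial-table columns.
#' @return A trial table data.frame; rejected rows (if any) in
#'   `attr(, "rejects")`.
#' @export
read_trial_table <- function(path) {
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop_delaymle(sprintf("cannot read '%s': %s", path,
                                          conditionMessage(e)),
                                  "delaymle_schema_error"))
  miss <- setdiff(trial_table_columns, names(raw))
  if (length(miss))
    stop_delaymle(paste("trial table lacks required column(s):",
                        paste(miss, collapse = ", ")),
                  "delaymle_schema_error")
  if (nrow(raw) == 0L)
    stop_delaymle("trial table is empty", "delaymle_schema_error")
  for (col in c("block", "trial_index", "cue_attended", "cue_ignored",
                "report", "peak_velocity"))
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- !is.finite(raw$report) |
    !raw$trial_type %in% c("V", "P", "VP_V", "VP_P") |
    !raw$block %in% c(1, 2) |
    !is.finite(raw$cue_attended) |
    (raw$trial_type %in% c("VP_V", "VP_P") & !is.finite(raw$cue_ignored))
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$block <- as.integer(out$block)
  if (any(bad)) {
    attr(out, "rejects") <- raw[bad, , drop = FALSE]
    message(sprintf("read_trial_table: %d malformed row(s) rejected (see attr 'rejects')",
                    sum(bad)))
  }
  out
}

#' Write a trial table to CSV
#'
#' @param trials A trial table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  miss <- setdiff(trial_table_columns, names(trials))
  if (length(miss))
    stop_delaymle(paste("trial table lacks required column(s):",
                        paste(miss, collapse = ", ")),
                  "delaymle_schema_error")
  utils::write.csv(trials[trial_table_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param experiment Design name (see [experiment_design()]).
#' @param n_subjects Cohort size (default 22, the scale of the original
#'   two-task cohort).
#' @param seed Master integer seed; cohort, trial, and permutation seeds are
#'   derived from it.
#' @param n_perm Number of permutations for inference (default 10000).
#' @param k_dynamic,recalib_rate Generator parameters forwarded to
#'   [cohort_config()].
#' @param out_dir Output directory.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(experiment = "exp1_static", n_subjects = 22L,
                       seed = 1L, n_perm = 10000L, k_dynamic = 0,
                       recalib_rate = 0, out_dir = ".") {
  structure(list(experiment = experiment, n_subjects = n_subjects,
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 k_dynamic = k_dynamic, recalib_rate = recalib_rate,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the simulate-analyse pipeline end to end
#'
#' Draws a cohort, simulates the chosen experiment, fits the integration-bias
#' model, and writes `trials.csv` plus `results.json` (bias table, group
#' statistics, and a provenance block echoing the configuration, derived
#' seeds, and package version) into `out_dir`. The same configuration always
#' reproduces byte-identical outputs.
#'
#' @param config A [run_config()] or a path to a JSON file with the same
#'   fields.
#' @return Invisibly, a list with the fitted `bias_fit` and the output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(run_config, cfg[intersect(names(cfg),
                                                names(formals(run_config)))])
  }
  stopifnot(inherits(config, "run_config"))
  seeds <- list(cohort = config$seed, trials = config$seed + 1000L,
                perm = config$seed + 2000L)
  cohort <- make_cohort(config$n_subjects,
                        cohort_config(k_dynamic = config$k_dynamic,
                                      recalib_rate = config$recalib_rate),
                        seed = seeds$cohort)
  design <- experiment_design(config$experiment)
  trials <- simulate_experiment(design, cohort, seed = seeds$trials)
  fit <- bias_fit(trials, n_perm = config$n_perm, seed = seeds$perm)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  trials_path <- file.path(config$out_dir, "trials.csv")
  results_path <- file.path(config$out_dir, "results.json")
  write_trial_table(trials, trials_path)
  results <- list(
    provenance = list(package = "delaymle",
                      version = as.character(utils::packageVersion("delaymle")),
                      config = unclass(config), seeds = seeds),
    conditions = list(
      VP_V = list(mean_bias_m = mean(fit$bias$bias_vpv),
                  p_value = fit$tests$VP_V$p_value),
      VP_P = list(mean_bias_m = mean(fit$bias$bias_vpp),
                  p_value = fit$tests$VP_P$p_value)),
    weights = list(w_hat_v = mean(fit$bias$w_hat_v),
                   w_hat_p = mean(fit$bias$w_hat_p)),
    regression = fit$regression,
    bias_table = fit$bias)
  jsonlite::write_json(results, results_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(list(fit = fit, trials = trials_path, results = results_path))
}
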