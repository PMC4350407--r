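#' Read and write trial tables
#'
#' Trial tables serialize as UTF-8 tab-separated files with a fixed header,
#' one row per trial. Schedule columns: `participant`, `run`, `trial`,
#' `context`, `coherence`, `correct_dir`, `onset_cue`, `onset_stim`,
#' `onset_feedback`, `iti`; behavioral datasets add `choice`, `correct`,
#' `reward`. Extra columns (e.g. trajectory exports) pass through.
#'
#' @param data tibble to write.
#' @param path file path.
#' @return `read_trial_table()` returns a tibble; `write_trial_table()`
#'   returns `path` invisibly.
#' @name trial-io
NULL

#' @rdname trial-io
#' @export
write_trial_table <- function(data, path) {
  readr::write_tsv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname trial-io
#' @export
read_trial_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Serialize a task configuration
#'
#' Configs round-trip through YAML (flat keys mirroring the
#' [task_config()] arguments). The solved ITI rate is recomputed on read.
#'
#' @param config a [task_config()].
#' @param path file path.
#' @return `read_task_config()` returns a [task_config()];
#'   `write_task_config()` returns `path` invisibly.
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "task_config"))
  fields <- config[c("coherence_levels", "reps_per_cell", "n_runs",
                     "iti_mean_s", "iti_min_s", "iti_max_s",
                     "cue_duration_s", "stim_duration_s",
                     "response_window_s", "feedback_duration_s")]
  fields$payoff <- lapply(config$payoff, as.list)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname config-io
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$payoff <- lapply(y$payoff, function(p) unlist(p))
  do.call(task_config, y)
}

#' Write per-participant fit results and the cohort comparison
#'
#' Fits go to a tab-separated table (participant, model, parameters, nll,
#' AIC, convergence); the cohort comparison summary goes to JSON.
#'
#' @param comparison a `cohort_comparison` from [compare_models()].
#' @param fits_path path for the TSV of per-participant fits.
#' @param summary_path path for the JSON summary.
#' @return invisibly, the two paths.
#' @export
write_cohort_comparison <- function(comparison, fits_path, summary_path) {
  stopifnot(inherits(comparison, "cohort_comparison"))
  readr::write_tsv(comparison$fits, fits_path)
  jsonlite::write_json(
    list(aic_by_model = as.list(comparison$aic_by_model),
         n_fit_better = as.list(comparison$n_fit_better),
         n_ties = comparison$n_ties,
         winner = comparison$winner),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fits_path, summary_path))
}
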