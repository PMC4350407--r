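#' Build a model-derived parametric-modulator event series
#'
#' Turns per-trial model quantities into fMRI parametric modulators:
#' \describe{
#'   \item{`abs_coherence`}{|signed coherence|, spanning stimulus onset to
#'     offset (0.2 s by default).}
#'   \item{`bias_amount`}{the trial-wise bias `|Q(up|c) - Q(down|c)|` from
#'     the trajectory, spanning trial (cue) onset to stimulus offset
#'     (1.0 + 0.2 s).}
#'   \item{`rpe_contextual` / `rpe_context_free`}{the signed reward
#'     prediction error of the matching model, spanning feedback onset to
#'     offset (1.5 s).}
#'   \item{`rpe_unsigned`}{|rpe| of the supplied trajectory (a surprise
#'     control regressor), same feedback window.}
#' }
#' Modulator weights are mean-centered, by default within run (first-level
#' GLMs are estimated per run).
#'
#' @param data trial table with onset columns and attached `task_config`
#'   (pass `config` explicitly otherwise); single participant.
#' @param trajectory [run_trajectory()] output for the same trials (needed
#'   for the bias/RPE modulators; its `model_kind` attribute must match a
#'   requested model-specific RPE).
#' @param which one of `"abs_coherence"`, `"bias_amount"`,
#'   `"rpe_contextual"`, `"rpe_context_free"`, `"rpe_unsigned"`.
#' @param center `"run"` (default), `"session"`, or `"none"`.
#' @param config a [task_config()]; defaults to `attr(data, "config")`.
#' @return A tibble `run`, `trial`, `onset`, `duration`, `weight`, ordered
#'   by run and onset.
#' @export
build_modulator_series <- function(data, trajectory = NULL,
                                   which = c("abs_coherence", "bias_amount",
                                             "rpe_contextual",
                                             "rpe_context_free",
                                             "rpe_unsigned"),
                                   center = c("run", "session", "none"),
                                   config = attr(data, "config")) {
  which <- match.arg(which)
  center <- match.arg(center)
  if (is.null(config) || !inherits(config, "task_config"))
    stop("a `task_config` is required (attribute or `config` argument)",
         call. = FALSE)
  needs_traj <- which != "abs_coherence"
  if (needs_traj) {
    if (is.null(trajectory))
      stop("`trajectory` is required for model-derived modulators", call. = FALSE)
    mk <- attr(trajectory, "model_kind")
    want <- switch(which, rpe_contextual = "context_dependent",
                   rpe_context_free = "context_free", NULL)
    if (!is.null(want) && !identical(mk, want))
      stop(sprintf("`%s` needs a trajectory from the %s model (got %s)",
                   which, want, mk), call. = FALSE)
    if (nrow(trajectory) != nrow(data) ||
        !isTRUE(all.equal(trajectory$trial, data$trial)))
      stop("trajectory rows do not match the dataset's trials", call. = FALSE)
  }
  out <- switch(
    which,
    abs_coherence = tibble::tibble(
      run = data$run, trial = data$trial,
      onset = data$onset_stim, duration = config$stim_duration_s,
      weight = abs(data$coherence)),
    bias_amount = tibble::tibble(
      run = data$run, trial = data$trial,
      onset = data$onset_cue,
      duration = config$cue_duration_s + config$stim_duration_s,
      weight = trajectory$bias_amount),
    tibble::tibble(  # the three RPE variants share the feedback window
      run = data$run, trial = data$trial,
      onset = data$onset_feedback, duration = config$feedback_duration_s,
      weight = if (which == "rpe_unsigned") abs(trajectory$rpe)
               else trajectory$rpe))
  if (center == "run") {
    out <- dplyr::mutate(dplyr::group_by(out, .data$run),
                         weight = .data$weight - mean(.data$weight))
    out <- dplyr::ungroup(out)
  } else if (center == "session") {
    out$weight <- out$weight - mean(out$weight)
  }
  dplyr::arrange(out, .data$run, .data$onset)
}

#' Write an event series as FSL three-column custom-timing files
#'
#' One whitespace-delimited text file per run (`onset duration weight`,
#' 6-decimal fixed format), named `<stem>_run<k>.txt` under `dir`.
#'
#' @param series tibble from [build_modulator_series()] (or any tibble with
#'   `run`, `onset`, `duration`, `weight`).
#' @param dir output directory (created if missing).
#' @param stem file-name stem, e.g. the regressor name.
#' @return invisibly, the written file paths.
#' @export
export_fsl_events <- function(series, dir, stem) {
  if (nrow(series) == 0) stop("empty event series", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- sort(unique(series$run))
  paths <- vapply(runs, function(r) {
    s <- series[series$run == r, ]
    s <- s[order(s$onset), ]
    path <- file.path(dir, sprintf("%s_run%d.txt", stem, r))
    writeLines(sprintf("%.6f %.6f %.6f", s$onset, s$duration, s$weight), path)
    path
  }, character(1))
  invisible(paths)
}

#' Read back an FSL three-column event file
#'
#' @param path file written by [export_fsl_events()].
#' @return tibble `onset`, `duration`, `weight`.
#' @export
read_fsl_events <- function(path) {
  m <- utils::read.table(path, col.names = c("onset", "duration", "weight"))
  tibble::as_tibble(m)
}

#' Export the nuisance boxcar regressors alongside the modulators
#'
#' Writes (1) an unmodulated trial-evoked boxcar (weight 1) spanning cue
#' onset to feedback offset — i.e. up to the next ITI onset — and (2) a
#' response boxcar for responded trials spanning stimulus onset to the end
#' of the response window. The data model carries no reaction times, so the
#' response boxcar uses the full response window; with measured RTs the
#' duration would end at the key press.
#'
#' @inheritParams build_modulator_series
#' @param dir output directory.
#' @param stem file-name stem prefix.
#' @return invisibly, the written file paths.
#' @export
export_trial_boxcars <- function(data, dir, stem = "task",
                                 config = attr(data, "config")) {
  if (is.null(config) || !inherits(config, "task_config"))
    stop("a `task_config` is required", call. = FALSE)
  trial_span <- config$cue_duration_s + config$response_window_s +
    config$feedback_duration_s
  trial_ev <- tibble::tibble(run = data$run, onset = data$onset_cue,
                             duration = trial_span, weight = 1)
  p1 <- export_fsl_events(trial_ev, dir, paste0(stem, "_trial"))
  responded <- if (!"choice" %in% names(data)) rep(TRUE, nrow(data))
               else data$choice != "none"
  p2 <- character(0)
  if (any(responded)) {
    resp_ev <- tibble::tibble(run = data$run[responded],
                              onset = data$onset_stim[responded],
                              duration = config$response_window_s, weight = 1)
    p2 <- export_fsl_events(resp_ev, dir, paste0(stem, "_response"))
  }
  invisible(c(p1, p2))
}

#' Export every standard modulator for one participant, with a manifest
#'
#' Convenience wrapper: builds and writes the |coherence|, bias-amount,
#' model RPE, and unsigned-RPE modulators plus the nuisance boxcars, and a
#' JSON manifest listing the files per run and regressor.
#'
#' @param data single-participant trial table with onsets and config.
#' @param trajectory matching [run_trajectory()] output.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
export_all_regressors <- function(data, trajectory, dir) {
  mk <- attr(trajectory, "model_kind")
  rpe_name <- if (identical(mk, "context_dependent")) "rpe_contextual"
              else "rpe_context_free"
  mods <- c("abs_coherence", "bias_amount", rpe_name, "rpe_unsigned")
  files <- list()
  for (m in mods) {
    series <- build_modulator_series(data, trajectory, which = m)
    files[[m]] <- as.vector(export_fsl_events(series, dir, m))
  }
  files[["boxcars"]] <- as.vector(export_trial_boxcars(data, dir))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(files, manifest, auto_unbox = FALSE, pretty = TRUE)
  invisible(manifest)
}
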