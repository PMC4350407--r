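#' Psychometric summary per context, run, and coherence level
#'
#' For every (context, run, coherence) cell, computes the per-participant
#' proportion of upward choices, then the group mean and its standard error
#' across participants. When a model trajectory is supplied, the model's
#' predicted P(up) is averaged over the same cells, so observed points can
#' be plotted against model curves.
#'
#' @param data stacked multi-participant trial table with `choice`.
#' @param trajectory optional stacked [run_trajectory()] output for the same
#'   trials (matched by participant and trial).
#' @return A tibble with columns `context`, `run`, `coherence`, `n`
#'   (total trials in the cell), `p_up` (group mean observed), `sem`
#'   (across participants; `NA` for a single participant), and `p_model`
#'   when a trajectory is given. Cells absent from the data are absent from
#'   the output.
#' @export
psychometric_by_run <- function(data, trajectory = NULL) {
  d <- tibble::as_tibble(data[, c("participant", "run", "context",
                                  "coherence", "choice", "trial")])
  d$up <- as.integer(d$choice == "up")
  if (!is.null(trajectory)) {
    tr <- tibble::as_tibble(trajectory[, c("participant", "trial", "p_up")])
    names(tr)[3] <- "p_pred"
    d <- dplyr::left_join(d, tr, by = c("participant", "trial"))
  } else d$p_pred <- NA_real_
  per_part <- dplyr::summarise(
    dplyr::group_by(d, .data$participant, .data$context, .data$run,
                    .data$coherence),
    n = dplyr::n(), p_model = mean(.data$p_pred), p_up = mean(.data$up),
    .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_part, .data$context, .data$run, .data$coherence),
    n = sum(.data$n),
    sem = if (dplyr::n() > 1) sd(.data$p_up) / sqrt(dplyr::n()) else NA_real_,
    p_up = mean(.data$p_up),
    p_model = mean(.data$p_model),
    .groups = "drop")
  if (is.null(trajectory)) out$p_model <- NULL
  dplyr::arrange(out, .data$context, .data$run, .data$coherence)
}

#' Residual autocorrelation diagnostics of a fitted learning model
#'
#' Per-trial residuals are `choice (0/1) - P(up)` under the supplied
#' trajectory. For each participant the standard sample autocorrelation
#' function (mean-centered, normalized by the lag-0 autocovariance) is
#' computed up to `max_lag`, then averaged with equal weights across
#' participants. The white-noise band is `+/- 1.96 / sqrt(T)` with `T` the
#' per-participant trial count: the 95% interval for autocorrelations of an
#' independent random process of the same length. Residuals of a correctly
#' specified model should stay inside the band at all nonzero lags.
#'
#' @param data stacked multi-participant trial table with `choice`.
#' @param trajectory stacked [run_trajectory()] output for the same trials.
#' @param max_lag largest lag (default 20; must be below the per-participant
#'   trial count).
#' @return A list of class `acf_report`: `acf` (tibble `lag`, `acf` with the
#'   group-mean autocorrelation, and per-participant columns in
#'   `acf_by_participant`), `band` (half-width), `n_trials`,
#'   `n_participants`.
#' @export
residual_acf <- function(data, trajectory, max_lag = 20) {
  d <- dplyr::left_join(
    tibble::as_tibble(data[, c("participant", "trial", "choice")]),
    tibble::as_tibble(trajectory[, c("participant", "trial", "p_up")]),
    by = c("participant", "trial"))
  d$resid <- as.integer(d$choice == "up") - d$p_up
  parts <- split(d, d$participant)
  n_t <- unique(vapply(parts, nrow, integer(1)))
  if (length(n_t) != 1)
    stop("participants have unequal trial counts", call. = FALSE)
  if (max_lag >= n_t)
    stop("`max_lag` must be smaller than the trial count per participant",
         call. = FALSE)
  acfs <- vapply(parts, function(p) {
    as.numeric(stats::acf(p$resid[order(p$trial)], lag.max = max_lag,
                          plot = FALSE, demean = TRUE)$acf)
  }, numeric(max_lag + 1))
  structure(
    list(acf = tibble::tibble(lag = 0:max_lag, acf = rowMeans(acfs)),
         acf_by_participant = acfs,
         band = 1.96 / sqrt(n_t),
         n_trials = n_t, n_participants = length(parts)),
    class = "acf_report")
}

#' @export
print.acf_report <- function(x, ...) {
  cat(sprintf("<acf_report> %d participants x %d trials, band +/- %.4f\n",
              x$n_participants, x$n_trials, x$band))
  out <- sum(abs(x$acf$acf[-1]) > x$band)
  cat(sprintf("  %d of %d nonzero lags outside the white-noise band\n",
              out, nrow(x$acf) - 1))
  invisible(x)
}

#' Group trajectory of indecision points per context
#'
#' Summarizes per-participant trajectories ([run_trajectory()] output with
#' `ip_<context>` columns) into a group mean and standard error of the
#' indecision point at every trial, separately per context — the bias
#' acquisition curve. Opposite payoff asymmetries should drive the two
#' contexts' curves apart in opposite signed directions as learning
#' proceeds.
#'
#' @param trajectories stacked [run_trajectory()] output with a
#'   `participant` column and equal trial counts per participant.
#' @return A tibble `trial`, `context`, `mean_ip`, `sem` (`NA` with a
#'   single participant, in which case a message notes the omitted band),
#'   with the trials-per-run count attached as attribute `"trials_per_run"`
#'   when a `run` column is present.
#' @export
indecision_trajectory_summary <- function(trajectories) {
  ip_cols <- grep("^ip_", names(trajectories), value = TRUE)
  if (length(ip_cols) == 0)
    stop("trajectories carry no `ip_<context>` columns", call. = FALSE)
  long <- tidyr::pivot_longer(
    trajectories[, c("participant", "trial", ip_cols)],
    dplyr::all_of(ip_cols), names_to = "context", names_prefix = "ip_",
    values_to = "ip")
  n_part <- length(unique(long$participant))
  if (n_part == 1)
    message("single participant: s.e.m. band omitted")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$trial, .data$context),
    mean_ip = mean(.data$ip),
    sem = if (n_part > 1) sd(.data$ip) / sqrt(n_part) else NA_real_,
    .groups = "drop")
  if ("run" %in% names(trajectories)) {
    tpr <- table(trajectories$run[trajectories$participant ==
                                    trajectories$participant[[1]]])
    attr(out, "trials_per_run") <- as.integer(tpr)
  }
  out
}

#' Plot helpers for the diagnostic summaries
#'
#' Simple \pkg{ggplot2} renderings of the psychometric summary (points:
#' observed, lines: model), the bias-acquisition curves, and the residual
#' autocorrelation report.
#'
#' @param summary output of [psychometric_by_run()] or
#'   [indecision_trajectory_summary()].
#' @param report output of [residual_acf()].
#' @return a `ggplot` object.
#' @name diagnostic-plots
NULL

#' @rdname diagnostic-plots
#' @export
plot_psychometric <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$coherence, y = .data$p_up,
                                    colour = .data$context)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~run, nrow = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "signed coherence", y = "P(choose up)") +
    ggplot2::theme_minimal()
  if (!is.null(summary$p_model))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$p_model))
  p
}

#' @rdname diagnostic-plots
#' @export
plot_indecision_trajectory <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$trial, y = .data$mean_ip,
                                    colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "indecision point (signed coherence)") +
    ggplot2::theme_minimal()
  if (!all(is.na(summary$sem)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_ip - .data$sem,
                   ymax = .data$mean_ip + .data$sem,
                   fill = .data$context),
      alpha = 0.2, colour = NA)
  tpr <- attr(summary, "trials_per_run")
  if (!is.null(tpr))
    p <- p + ggplot2::geom_vline(xintercept = cumsum(tpr), linetype = "dashed",
                                 colour = "grey50")
  p
}

#' @rdname diagnostic-plots
#' @export
plot_acf_report <- function(report) {
  ggplot2::ggplot(report$acf, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * report$band,
                        linetype = "dashed") +
    ggplot2::labs(x = "lag (trials)", y = "residual autocorrelation") +
    ggplot2::theme_minimal()
}
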