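#' Task configuration for the two-context motion-discrimination reward task
#'
#' Defines the scanner task: two reward contexts crossed with seven signed
#' motion-coherence levels, an asymmetric payoff table that is opposite
#' between the contexts, event timing, and a truncated-exponential
#' inter-trial interval (ITI) distribution. Coherence is represented as a
#' signed proportion in \[-1, 1\] (64\% coherent upward motion is +0.64).
#'
#' The ITI distribution is an exponential shifted to `iti_min_s` and
#' truncated at `iti_max_s`; its rate is solved numerically at construction
#' time so that the truncated mean equals `iti_mean_s`, and cached in the
#' returned object.
#'
#' @param coherence_levels signed coherence proportions; must be symmetric
#'   about 0 and include 0.
#' @param reps_per_cell repetitions of every (context, coherence) cell.
#' @param n_runs number of scanning runs the trials are split across.
#' @param payoff named list, one element per context, each a named numeric
#'   vector `c(up = , down = )` of reward points for a *correct* choice of
#'   that direction in that context. Incorrect or missing responses always
#'   earn 0. The asymmetry must be opposite between the two contexts.
#' @param iti_mean_s,iti_min_s,iti_max_s target mean and range (seconds) of
#'   the truncated-exponential ITI.
#' @param cue_duration_s duration of the reward-context cue (colored
#'   fixation cross).
#' @param stim_duration_s duration of the random-dot motion stimulus.
#' @param response_window_s response deadline, measured from stimulus onset.
#' @param feedback_duration_s duration of the reward-points feedback display.
#'
#' @return An object of class `task_config` (a list), including the solved
#'   ITI rate in `$iti_rate`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials  # 280 under the defaults
#' @export
task_config <- function(coherence_levels = c(-0.64, -0.12, -0.04, 0, 0.04, 0.12, 0.64),
                        reps_per_cell = 20,
                        n_runs = 5,
                        payoff = list(A = c(up = 2, down = 1),
                                      B = c(up = 1, down = 2)),
                        iti_mean_s = 4.0,
                        iti_min_s = 2.7,
                        iti_max_s = 12.7,
                        cue_duration_s = 1.0,
                        stim_duration_s = 0.2,
                        response_window_s = 0.8,
                        feedback_duration_s = 1.5) {
  coherence_levels <- sort(unique(coherence_levels))
  if (!0 %in% coherence_levels)
    stop("`coherence_levels` must include 0", call. = FALSE)
  if (!isTRUE(all.equal(sort(-coherence_levels), coherence_levels)))
    stop("`coherence_levels` must be symmetric about 0", call. = FALSE)
  if (any(abs(coherence_levels) > 1))
    stop("coherence is a signed proportion; levels must lie in [-1, 1]", call. = FALSE)
  if (length(payoff) != 2L || is.null(names(payoff)) || anyDuplicated(names(payoff)))
    stop("`payoff` must be a named list with one element per context (2 contexts)",
         call. = FALSE)
  for (ctx in names(payoff)) {
    p <- payoff[[ctx]]
    if (!all(c("up", "down") %in% names(p)) || any(!is.finite(p)))
      stop("each payoff entry needs finite `up` and `down` points", call. = FALSE)
  }
  asym <- vapply(payoff, function(p) p[["up"]] - p[["down"]], numeric(1))
  if (any(asym == 0) || sign(asym[[1]]) != -sign(asym[[2]]))
    stop("payoff asymmetry must be nonzero and opposite between the two contexts",
         call. = FALSE)
  n_cells <- 2L * length(coherence_levels)
  n_trials <- n_cells * reps_per_cell
  if (n_trials %% n_runs != 0)
    stop(sprintf("total trial count %d is not divisible by n_runs = %d",
                 n_trials, n_runs), call. = FALSE)
  if (!(iti_min_s <= iti_mean_s && iti_mean_s <= iti_max_s))
    stop("need iti_min_s <= iti_mean_s <= iti_max_s", call. = FALSE)

  cfg <- structure(
    list(coherence_levels = coherence_levels,
         reps_per_cell = as.integer(reps_per_cell),
         n_runs = as.integer(n_runs),
         payoff = payoff,
         contexts = names(payoff),
         n_trials = as.integer(n_trials),
         trials_per_run = as.integer(n_trials / n_runs),
         iti_mean_s = iti_mean_s, iti_min_s = iti_min_s, iti_max_s = iti_max_s,
         cue_duration_s = cue_duration_s,
         stim_duration_s = stim_duration_s,
         response_window_s = response_window_s,
         feedback_duration_s = feedback_duration_s),
    class = "task_config")
  cfg$iti_rate <- .iti_rate(iti_mean_s, iti_min_s, iti_max_s)
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d trials: %d contexts x %d coherence levels x %d reps, %d runs of %d\n",
              x$n_trials, length(x$contexts), length(x$coherence_levels),
              x$reps_per_cell, x$n_runs, x$trials_per_run))
  cat(sprintf("  ITI ~ truncated exp, mean %.2f s on [%.2f, %.2f] s\n",
              x$iti_mean_s, x$iti_min_s, x$iti_max_s))
  for (ctx in x$contexts)
    cat(sprintf("  context %s payoff (correct): up %g, down %g\n",
                ctx, x$payoff[[ctx]][["up"]], x$payoff[[ctx]][["down"]]))
  invisible(x)
}

# Mean of Exp(rate) truncated to [0, b]; rate may be negative (density
# increasing towards b). Continuous at rate -> 0 with limit b/2.
.truncexp_mean <- function(rate, b) {
  if (abs(rate * b) < 1e-9) return(b / 2)
  1 / rate - b * exp(-rate * b) / (1 - exp(-rate * b))
}

# Solve the rate so the mean of the shifted, truncated exponential on
# [lo, hi] equals `mean`. Returns NA rate for the degenerate lo == hi case.
.iti_rate <- function(mean, lo, hi) {
  if (lo == hi) return(NA_real_)
  if (!(mean > lo && mean < hi))
    stop("requested ITI mean must lie strictly inside (iti_min_s, iti_max_s)",
         call. = FALSE)
  b <- hi - lo
  target <- mean - lo
  f <- function(r) .truncexp_mean(r, b) - target
  # target < b/2 needs a decaying density (rate > 0), target > b/2 a rising one
  if (abs(target - b / 2) < 1e-12) return(0)
  interval <- if (target < b / 2) c(1e-8, 500 / b) else c(-500 / b, -1e-8)
  uniroot(f, interval, tol = 1e-12)$root
}

#' Draw inter-trial intervals from the task's truncated-exponential ITI
#'
#' @param n number of draws.
#' @param config a [task_config()].
#' @param seed optional integer seed; when supplied the draws are
#'   reproducible and the caller's RNG state is untouched.
#' @return numeric vector of ITIs in seconds, each in
#'   `[config$iti_min_s, config$iti_max_s]`.
#' @examples
#' mean(sample_iti(1e4, task_config(), seed = 1))  # close to 4 s
#' @export
sample_iti <- function(n, config, seed = NULL) {
  stopifnot(inherits(config, "task_config"), n >= 0)
  draw <- function() {
    lo <- config$iti_min_s; hi <- config$iti_max_s
    if (lo == hi) return(rep(lo, n))
    r <- config$iti_rate
    u <- runif(n)
    if (r == 0) return(lo + u * (hi - lo))
    lo - log(1 - u * (1 - exp(-r * (hi - lo)))) / r
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Configuration of the pre-scan practice session
#'
#' The practice session has nine signed coherence levels, no reward contexts
#' and no payoffs; trials follow each other immediately (a 1.5 s fixation
#' cross, a 200 ms stimulus, a 600 ms response window, and 1.5 s of error
#' feedback on incorrect or slow trials).
#'
#' @param coherence_levels signed coherence proportions (symmetric, with 0).
#' @param reps_per_level repetitions of every coherence level.
#' @param n_blocks number of equally sized blocks.
#' @return An object of class `practice_config`.
#' @export
practice_config <- function(coherence_levels = c(-0.80, -0.64, -0.12, -0.06, 0,
                                                 0.06, 0.12, 0.64, 0.80),
                            reps_per_level = 60,
                            n_blocks = 6) {
  coherence_levels <- sort(unique(coherence_levels))
  if (!0 %in% coherence_levels ||
      !isTRUE(all.equal(sort(-coherence_levels), coherence_levels)))
    stop("practice coherence levels must be symmetric about 0 and include 0",
         call. = FALSE)
  n_trials <- length(coherence_levels) * reps_per_level
  if (n_trials %% n_blocks != 0)
    stop("practice trial count must divide evenly into blocks", call. = FALSE)
  structure(
    list(coherence_levels = coherence_levels,
         reps_per_level = as.integer(reps_per_level),
         n_blocks = as.integer(n_blocks),
         n_trials = as.integer(n_trials),
         trials_per_block = as.integer(n_trials / n_blocks),
         fixation_duration_s = 1.5, stim_duration_s = 0.2,
         response_window_s = 0.6, feedback_duration_s = 1.5),
    class = "practice_config")
}
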