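#' Build a counterbalanced trial schedule for the scanner task
#'
#' Every (context, coherence) cell appears exactly `reps_per_cell` times over
#' the session. When `reps_per_cell` divides `n_runs` evenly (the default:
#' 20 reps over 5 runs, i.e. 4 per cell per run) each run contains the same
#' cell composition and the order within a run is a seeded uniform shuffle;
#' otherwise trials are randomly split into equal-sized runs. The correct
#' direction of 0%-coherence trials is a fair, seeded Bernoulli draw per
#' trial. Event onsets accumulate ITI draws and the fixed event durations.
#'
#' @param config a [task_config()].
#' @param seed integer seed controlling trial order, 0%-coherence correct
#'   directions, and ITI draws.
#' @param participant_id identifier stored in the `participant` column.
#' @return A tibble with one row per trial and columns `participant`, `run`,
#'   `trial` (1-based within participant), `context`, `coherence`,
#'   `correct_dir`, `onset_cue`, `onset_stim`, `onset_feedback`, `iti`
#'   (onsets in seconds from run start). The `task_config` is attached as
#'   attribute `"config"`.
#' @examples
#' sched <- build_trial_schedule(task_config(), seed = 1)
#' nrow(sched)          # 280
#' table(sched$run)     # 56 per run
#' @export
build_trial_schedule <- function(config, seed, participant_id = "p01") {
  stopifnot(inherits(config, "task_config"))
  withr::with_seed(seed, {
    cells <- tidyr::expand_grid(context = config$contexts,
                                coherence = config$coherence_levels)
    per_run_reps <- config$reps_per_cell / config$n_runs
    if (per_run_reps == floor(per_run_reps)) {
      # exact cell balance within every run
      runs <- lapply(seq_len(config$n_runs), function(r) {
        tr <- cells[rep(seq_len(nrow(cells)), per_run_reps), ]
        tr <- tr[sample.int(nrow(tr)), ]
        tr$run <- r
        tr
      })
      trials <- dplyr::bind_rows(runs)
    } else {
      trials <- cells[rep(seq_len(nrow(cells)), config$reps_per_cell), ]
      trials <- trials[sample.int(nrow(trials)), ]
      trials$run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
    }
    trials$participant <- participant_id
    trials$trial <- seq_len(nrow(trials))
    trials$correct_dir <- ifelse(
      trials$coherence > 0, "up",
      ifelse(trials$coherence < 0, "down",
             sample(c("up", "down"), nrow(trials), replace = TRUE)))
    trials$iti <- sample_iti(nrow(trials), config)

    # onsets restart at 0 within each run; each trial spans
    # iti + cue + response window (stimulus included) + feedback
    span <- config$cue_duration_s + config$response_window_s +
      config$feedback_duration_s
    trials <- dplyr::group_by(trials, .data$run)
    trials <- dplyr::mutate(
      trials,
      onset_cue = cumsum(.data$iti) + (dplyr::row_number() - 1) * span,
      onset_stim = .data$onset_cue + config$cue_duration_s,
      onset_feedback = .data$onset_stim + config$response_window_s)
    trials <- dplyr::ungroup(trials)
  })
  out <- tibble::as_tibble(trials[, c("participant", "run", "trial", "context",
                                      "coherence", "correct_dir", "onset_cue",
                                      "onset_stim", "onset_feedback", "iti")])
  attr(out, "config") <- config
  out
}

#' Build a practice-session trial schedule
#'
#' @param config a [practice_config()].
#' @param seed integer seed.
#' @param participant_id identifier stored in the `participant` column.
#' @return A tibble with columns `participant`, `block`, `trial`,
#'   `coherence`, `correct_dir` (no reward contexts, no payoffs).
#' @export
build_practice_schedule <- function(config = practice_config(), seed,
                                    participant_id = "p01") {
  stopifnot(inherits(config, "practice_config"))
  withr::with_seed(seed, {
    per_block <- config$reps_per_level / config$n_blocks
    lv <- config$coherence_levels
    if (per_block == floor(per_block)) {
      blocks <- lapply(seq_len(config$n_blocks), function(b) {
        coh <- rep(lv, per_block)
        tibble::tibble(block = b, coherence = coh[sample.int(length(coh))])
      })
      trials <- dplyr::bind_rows(blocks)
    } else {
      coh <- rep(lv, config$reps_per_level)
      coh <- coh[sample.int(length(coh))]
      trials <- tibble::tibble(block = rep(seq_len(config$n_blocks),
                                           each = config$trials_per_block),
                               coherence = coh)
    }
    trials$participant <- participant_id
    trials$trial <- seq_len(nrow(trials))
    trials$correct_dir <- ifelse(
      trials$coherence > 0, "up",
      ifelse(trials$coherence < 0, "down",
             sample(c("up", "down"), nrow(trials), replace = TRUE)))
  })
  out <- trials[, c("participant", "block", "trial", "coherence", "correct_dir")]
  attr(out, "config") <- config
  out
}

#' Reward points earned by a choice
#'
#' Applies the asymmetric payoff table: a correct choice earns the context's
#' points for that direction (high in the context's favored direction, low in
#' the other); an incorrect choice or a missing response (`"none"`) earns 0.
#'
#' @param context character vector of context labels (names of
#'   `config$payoff`).
#' @param choice character vector, `"up"`, `"down"`, or `"none"`.
#' @param correct_dir character vector of correct directions.
#' @param config a [task_config()].
#' @return numeric vector of reward points.
#' @export
assign_outcome <- function(context, choice, correct_dir, config) {
  stopifnot(inherits(config, "task_config"))
  n <- length(choice)
  context <- rep_len(context, n)
  correct_dir <- rep_len(correct_dir, n)
  if (!all(context %in% config$contexts))
    stop("unknown context label(s): ",
         paste(setdiff(context, config$contexts), collapse = ", "), call. = FALSE)
  if (!all(choice %in% c("up", "down", "none")))
    stop("choice must be 'up', 'down' or 'none'", call. = FALSE)
  r <- numeric(n)
  hit <- choice != "none" & choice == correct_dir
  if (any(hit)) {
    r[hit] <- mapply(function(ctx, ch) config$payoff[[ctx]][[ch]],
                     context[hit], choice[hit])
  }
  r
}
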