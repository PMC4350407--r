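#' Negative log-likelihood of a choice dataset under a learning model
#'
#' The likelihood of an observed choice sequence is the product over trials
#' of the model's probability of the chosen direction, evaluated along the
#' same forward pass as [run_trajectory()]. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` inside the likelihood only.
#'
#' @inheritParams run_trajectory
#' @return negative log-likelihood in nats (a nonnegative scalar).
#' @examples
#' # one trial at P(chosen) = 0.5 gives log(2)
#' d <- tibble::tibble(context = "A", coherence = 0, choice = "up", reward = 0)
#' negative_log_likelihood(d, model_params(1, 4, 0.1), "context_free")
#' @export
negative_log_likelihood <- function(data, params,
                                    model_kind = c("context_dependent", "context_free"),
                                    q_init = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(params, "model_params"))
  if (nrow(data) == 0) stop("dataset has zero trials", call. = FALSE)
  codes <- .forward_codes(data, model_kind)
  if (anyNA(codes$choice_up))
    stop("every trial needs an observed 'up'/'down' choice", call. = FALSE)
  qv <- .q_init_vector(q_init, model_kind, codes$contexts)
  .rl_forward_cpp(codes$ctx_idx, codes$choice_up,
                  as.numeric(data$reward), as.numeric(data$coherence),
                  params$beta0, params$beta1, params$alpha,
                  qv, model_kind == "context_dependent")$nll
}

#' Fit a learning model to one participant by maximum likelihood
#'
#' Minimizes the negative log-likelihood with Nelder-Mead simplex search
#' from `n_starts` seeded initializations (the first start is a fixed
#' canonical point, the rest random). The learning rate is optimized through
#' a logistic reparameterization so that `alpha` stays in \[0, 1\];
#' `beta0` and `beta1` are unconstrained.
#'
#' @inheritParams negative_log_likelihood
#' @param n_starts number of optimization restarts (default 10).
#' @param seed integer seed for the random starts.
#' @return A one-row tibble: `participant`, `model_kind`, `beta0`, `beta1`,
#'   `alpha`, `nll`, `k` (free parameters, 3), `aic` (`2*nll + 2k`),
#'   `converged`, `n_trials`.
#' @export
fit_participant <- function(data,
                            model_kind = c("context_dependent", "context_free"),
                            q_init = NULL, n_starts = 10, seed = 1) {
  model_kind <- match.arg(model_kind)
  if (nrow(data) < 50)
    warning("fewer than 50 trials; maximum-likelihood estimates may be unstable")
  codes <- .forward_codes(data, model_kind)
  if (anyNA(codes$choice_up))
    stop("every trial needs an observed 'up'/'down' choice", call. = FALSE)
  qv <- .q_init_vector(q_init, model_kind, codes$contexts)
  cd <- model_kind == "context_dependent"
  reward <- as.numeric(data$reward)
  coh <- as.numeric(data$coherence)

  obj <- function(par) {
    .rl_forward_cpp(codes$ctx_idx, codes$choice_up, reward, coh,
                    par[1], par[2], plogis(par[3]), qv, cd)$nll
  }
  starts <- rbind(
    c(1, 3, qlogis(0.05)),
    if (n_starts > 1) withr::with_seed(seed, cbind(
      runif(n_starts - 1, -1, 3),
      runif(n_starts - 1, 0, 8),
      runif(n_starts - 1, qlogis(0.002), qlogis(0.5)))))
  fits <- apply(starts, 1, function(s) {
    tryCatch(optim(s, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("optimization failed from every start (", n_starts, " starts)",
         call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  nll <- best$value
  k <- 3L
  tibble::tibble(
    participant = if ("participant" %in% names(data)) data$participant[[1]] else NA_character_,
    model_kind = model_kind,
    beta0 = best$par[1], beta1 = best$par[2], alpha = plogis(best$par[3]),
    nll = nll, k = k, aic = 2 * nll + 2 * k,
    converged = best$convergence == 0L,
    n_trials = nrow(data))
}

#' Group AIC over a cohort of per-participant fits
#'
#' `AIC = sum over participants of (2 * nll + 2k)`: standard per-participant
#' AIC summed across the cohort, with `k = 3` free parameters per
#' participant and model.
#'
#' @param fits tibble of [fit_participant()] rows sharing one `model_kind`.
#' @return group AIC (scalar).
#' @export
aic_group <- function(fits) {
  if (nrow(fits) == 0) stop("empty fit list", call. = FALSE)
  if (length(unique(fits$model_kind)) != 1)
    stop("all fits must share one model_kind", call. = FALSE)
  sum(2 * fits$nll + 2 * fits$k)
}

#' Fit and compare learning models across a cohort
#'
#' Fits every requested model to every participant, computes group AIC per
#' model and per-participant winner counts (ties, defined as per-participant
#' AIC differences below `tie_tol`, are counted separately as unresolved).
#'
#' @param data stacked multi-participant trial table (or a list of
#'   per-participant tibbles).
#' @param model_kinds models to fit.
#' @param q_init,n_starts,seed passed to [fit_participant()]; sub-seeds are
#'   derived per participant.
#' @param tie_tol absolute per-participant AIC difference below which a
#'   comparison counts as a tie.
#' @return A list of class `cohort_comparison`: `fits` (all per-participant
#'   rows), `aic_by_model` (named vector), `n_fit_better` (named counts),
#'   `n_ties`, `winner` (model with the lowest group AIC).
#' @export
compare_models <- function(data,
                           model_kinds = c("context_dependent", "context_free"),
                           q_init = NULL, n_starts = 10, seed = 1,
                           tie_tol = 1e-6) {
  parts <- if (is.data.frame(data)) split_participants(data) else data
  seeds <- derive_seeds(seed, length(parts) * length(model_kinds))
  i <- 0L
  fits <- dplyr::bind_rows(lapply(model_kinds, function(mk) {
    dplyr::bind_rows(lapply(parts, function(d) {
      i <<- i + 1L
      fit_participant(d, mk, q_init = q_init, n_starts = n_starts,
                      seed = seeds[i])
    }))
  }))
  aic_by_model <- vapply(model_kinds, function(mk)
    aic_group(fits[fits$model_kind == mk, ]), numeric(1))
  wide <- tidyr::pivot_wider(fits[, c("participant", "model_kind", "aic")],
                             names_from = "model_kind", values_from = "aic")
  n_fit_better <- stats::setNames(integer(length(model_kinds)), model_kinds)
  n_ties <- 0L
  if (length(model_kinds) == 2) {
    d_aic <- wide[[model_kinds[1]]] - wide[[model_kinds[2]]]
    n_ties <- sum(abs(d_aic) < tie_tol)
    n_fit_better[model_kinds[1]] <- sum(d_aic < -tie_tol)
    n_fit_better[model_kinds[2]] <- sum(d_aic > tie_tol)
  } else {
    for (p in seq_len(nrow(wide))) {
      a <- unlist(wide[p, model_kinds])
      if (sum(abs(a - min(a)) < tie_tol) > 1) n_ties <- n_ties + 1L
      else n_fit_better[names(which.min(a))] <-
          n_fit_better[names(which.min(a))] + 1L
    }
  }
  structure(list(fits = fits, aic_by_model = aic_by_model,
                 n_fit_better = n_fit_better, n_ties = n_ties,
                 winner = names(which.min(aic_by_model))),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  for (mk in names(x$aic_by_model))
    cat(sprintf("  %-18s group AIC %10.2f  better for %d participant(s)\n",
                mk, x$aic_by_model[[mk]], x$n_fit_better[[mk]]))
  if (x$n_ties > 0) cat(sprintf("  ties (unresolved): %d\n", x$n_ties))
  cat("  winner:", x$winner, "\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_agents` agents at known parameters, refits each one, and
#' tabulates the estimate distribution against the truth: per-parameter
#' median, bias of the median, RMSE, and coverage of a central plausibility
#' interval.
#'
#' @param true_params generating [model_params()].
#' @param model_kind generating and fitted model.
#' @param n_agents number of simulated agents (>= 2).
#' @param config a [task_config()] defining the schedules.
#' @param seed master seed.
#' @param n_starts optimization restarts per fit.
#' @return A list: `estimates` (one fit row per agent) and `summary`
#'   (tibble with `parameter`, `truth`, `median`, `bias`, `rmse`).
#' @export
recover_parameters <- function(true_params,
                               model_kind = c("context_dependent", "context_free"),
                               n_agents = 23, config = task_config(), seed = 1,
                               n_starts = 10) {
  model_kind <- match.arg(model_kind)
  if (n_agents < 2) stop("need at least 2 agents", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  cohort <- simulate_cohort(config, true_params, model_kind,
                            n_agents = n_agents, seed = seeds[1])
  fit_seeds <- derive_seeds(seeds[2], n_agents)
  parts <- split_participants(cohort)
  est <- dplyr::bind_rows(lapply(seq_along(parts), function(i)
    fit_participant(parts[[i]], model_kind, n_starts = n_starts,
                    seed = fit_seeds[i])))
  truth_val <- c(beta0 = true_params$beta0, beta1 = true_params$beta1,
                 alpha = true_params$alpha)
  summ <- dplyr::bind_rows(lapply(names(truth_val), function(p) {
    x <- est[[p]]
    tibble::tibble(parameter = p, truth = truth_val[[p]],
                   median = stats::median(x),
                   bias = stats::median(x) - truth_val[[p]],
                   rmse = sqrt(mean((x - truth_val[[p]])^2)))
  }))
  list(estimates = est, summary = summ)
}
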