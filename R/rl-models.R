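#' Parameters of the reinforcement-learning choice model
#'
#' `beta0` weighs the learned value difference between the two motion
#' directions, `beta1` weighs the signed motion coherence (per unit signed
#' proportion), and `alpha` is the constant learning rate of the delta-rule
#' value update, constrained to \[0, 1\].
#'
#' @param beta0,beta1 finite real weights.
#' @param alpha learning rate in \[0, 1\].
#' @return An object of class `model_params`.
#' @examples
#' model_params(beta0 = 0.81, beta1 = 4.01, alpha = 0.02)
#' @export
model_params <- function(beta0, beta1, alpha) {
  if (!all(is.finite(c(beta0, beta1, alpha))))
    stop("model parameters must be finite", call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  structure(list(beta0 = beta0, beta1 = beta1, alpha = alpha),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> beta0 = %g, beta1 = %g, alpha = %g\n",
              x$beta0, x$beta1, x$alpha))
  invisible(x)
}

#' Action-value state of a learning model
#'
#' The context-dependent model keeps one value per (context, direction) pair
#' (4 entries); the context-free model keeps one value per direction
#' (2 entries). Values are in reward-point units.
#'
#' @param model_kind `"context_dependent"` or `"context_free"`.
#' @param contexts context labels (used by the context-dependent model).
#' @param q initial values: a scalar recycled to all entries, or a full named
#'   vector in the state's own ordering (see [value_state()] printing).
#' @return An object of class `value_state`: a named numeric vector
#'   `<context>.<direction>` (or `<direction>`), direction order
#'   `down`, `up`, with the model kind and contexts as attributes.
#' @export
value_state <- function(model_kind = c("context_dependent", "context_free"),
                        contexts = c("A", "B"), q = 0) {
  model_kind <- match.arg(model_kind)
  nm <- if (model_kind == "context_dependent") {
    as.vector(vapply(contexts, function(ctx) paste(ctx, c("down", "up"), sep = "."),
                     character(2)))
  } else c("down", "up")
  if (length(q) == 1L) q <- rep(q, length(nm))
  if (length(q) != length(nm) || any(!is.finite(q)))
    stop(sprintf("`q` must be finite, scalar or length %d", length(nm)),
         call. = FALSE)
  if (!is.null(names(q))) q <- q[nm]
  structure(stats::setNames(as.numeric(q), nm),
            model_kind = model_kind, contexts = contexts, class = "value_state")
}

#' @export
print.value_state <- function(x, ...) {
  cat(sprintf("<value_state: %s>\n", attr(x, "model_kind")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

.state_idx <- function(state, context, direction) {
  if (attr(state, "model_kind") == "context_dependent")
    match(paste(context, direction, sep = "."), names(state))
  else match(direction, names(state))
}

#' Map a practice-session bias intercept to initial action values
#'
#' Participants may enter the task with a pre-existing bias, visible as a
#' nonzero intercept `b` of a plain logistic psychometric fit to practice
#' choices (`P(up) = plogis(b + beta1 * S)`). Under the value model the same
#' shift corresponds to an initial value difference `delta Q = b / beta0`;
#' this helper places that difference on the `up` value of every context.
#'
#' @param intercept psychometric intercept `b` (log-odds of choosing up at
#'   zero coherence and equal values).
#' @param params a [model_params()] (only `beta0` is used; must be nonzero).
#' @param model_kind,contexts passed to [value_state()].
#' @return A [value_state()] with `Q(up) = intercept / beta0` and
#'   `Q(down) = 0` in every context.
#' @export
q_init_from_intercept <- function(intercept, params,
                                  model_kind = c("context_dependent", "context_free"),
                                  contexts = c("A", "B")) {
  model_kind <- match.arg(model_kind)
  if (params$beta0 == 0)
    stop("`beta0` must be nonzero to translate an intercept into values",
         call. = FALSE)
  st <- value_state(model_kind, contexts, q = 0)
  st[grepl("(^|\\.)up$", names(st))] <- intercept / params$beta0
  st
}

#' Probability of choosing upward motion
#'
#' The psychometric rule: `P(up) = plogis(beta0 * (Q(up) - Q(down)) +
#' beta1 * S)`, with `S` the signed coherence (positive = upward) and the
#' Q values taken from the trial's reward context (context-dependent model)
#' or shared across contexts (context-free model). P(up) is strictly
#' increasing in both the coherence and the value advantage of `up`.
#'
#' @param state a [value_state()].
#' @param context context label of the current trial (ignored by the
#'   context-free model).
#' @param coherence signed coherence proportion in \[-1, 1\].
#' @param params a [model_params()].
#' @return probability in (0, 1).
#' @examples
#' st <- value_state("context_free")
#' choice_probability(st, "A", 0, model_params(1, 4, 0.02))  # 0.5
#' @export
choice_probability <- function(state, context, coherence, params) {
  stopifnot(inherits(state, "value_state"))
  if (!is.finite(coherence))
    stop("`coherence` must be finite", call. = FALSE)
  dq <- state[.state_idx(state, context, "up")] -
    state[.state_idx(state, context, "down")]
  unname(plogis(params$beta0 * dq + params$beta1 * coherence))
}

#' Delta-rule value updates
#'
#' After feedback `r` on a trial where direction `choice` was taken, the
#' reward prediction error is `rpe = r - Q(choice)` and the chosen value
#' moves by `alpha * rpe`; no other entry changes. The context-dependent
#' update conditions `Q` on the trial's reward context, the context-free
#' update ignores it. The returned `rpe` is the raw prediction error,
#' before scaling by the learning rate.
#'
#' @param state a [value_state()] of the matching kind.
#' @param context context label of the trial (context-dependent only).
#' @param choice chosen direction, `"up"` or `"down"`.
#' @param reward reward points received.
#' @param alpha learning rate in \[0, 1\].
#' @return A list with elements `state` (updated [value_state()]) and `rpe`.
#' @examples
#' st <- value_state("context_dependent")
#' update_context_dependent(st, "A", "up", reward = 2, alpha = 0.02)
#' @name value-updates
NULL

#' @rdname value-updates
#' @export
update_context_dependent <- function(state, context, choice, reward, alpha) {
  stopifnot(inherits(state, "value_state"))
  if (attr(state, "model_kind") != "context_dependent")
    stop("state is not context-dependent", call. = FALSE)
  .delta_update(state, .state_idx(state, context, choice), reward, alpha)
}

#' @rdname value-updates
#' @export
update_context_free <- function(state, choice, reward, alpha) {
  stopifnot(inherits(state, "value_state"))
  if (attr(state, "model_kind") != "context_free")
    stop("state is not context-free", call. = FALSE)
  .delta_update(state, .state_idx(state, NULL, choice), reward, alpha)
}

.delta_update <- function(state, i, reward, alpha) {
  if (is.na(i)) stop("unknown context or direction label", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  rpe <- reward - state[[i]]
  state[[i]] <- state[[i]] + alpha * rpe
  list(state = state, rpe = unname(rpe))
}

#' Indecision point of the psychometric function
#'
#' The signed coherence at which both directions are equally likely:
#' `S* = -beta0 * (Q(up) - Q(down)) / beta1`. A negative indecision point
#' means the observer chooses "up" even at mildly downward coherence — a
#' bias toward up. The point may lie outside the tested coherence range.
#'
#' @inheritParams choice_probability
#' @return signed coherence proportion.
#' @export
indecision_point <- function(state, context, params) {
  stopifnot(inherits(state, "value_state"))
  if (params$beta1 == 0)
    stop("indecision point is undefined when `beta1` is 0", call. = FALSE)
  dq <- state[.state_idx(state, context, "up")] -
    state[.state_idx(state, context, "down")]
  unname(-params$beta0 * dq / params$beta1)
}

# Shared plumbing: map a trial table to the integer codes the C++ forward
# pass expects. Context order comes from the attached config when present.
.forward_codes <- function(data, model_kind) {
  contexts <- .data_contexts(data)
  ctx_idx <- if (model_kind == "context_dependent") {
    match(data$context, contexts) - 1L
  } else rep(0L, nrow(data))
  choice_up <- rep(NA_integer_, nrow(data))
  if ("choice" %in% names(data)) {
    choice_up[data$choice == "up"] <- 1L
    choice_up[data$choice == "down"] <- 0L
  }
  list(contexts = contexts, ctx_idx = as.integer(ctx_idx),
       choice_up = choice_up)
}

.data_contexts <- function(data) {
  cfg <- attr(data, "config")
  if (!is.null(cfg) && inherits(cfg, "task_config")) return(cfg$contexts)
  if (!"context" %in% names(data)) return("A")
  sort(unique(data$context))
}

.q_init_vector <- function(q_init, model_kind, contexts) {
  if (is.null(q_init)) q_init <- value_state(model_kind, contexts, q = 0)
  if (!inherits(q_init, "value_state"))
    q_init <- value_state(model_kind, contexts, q = q_init)
  if (attr(q_init, "model_kind") != model_kind)
    stop("`q_init` is a ", attr(q_init, "model_kind"),
         " state; the model is ", model_kind, call. = FALSE)
  as.numeric(q_init)
}

#' Deterministic per-trial trajectory of a fitted (or assumed) model
#'
#' Runs the value learner forward over an observed dataset: for every trial
#' it records the pre-choice value state, the model's P(up), the reward
#' prediction error after feedback, the trial-wise bias amount
#' `|Q(up|c) - Q(down|c)|` in the trial's own context, and the indecision
#' point — both for the trial's context (`indecision`) and for every context
#' (`ip_<context>` columns), so the bias trajectory of each context can be
#' followed on every trial.
#'
#' @param data trial table with columns `context`, `coherence`, `choice`,
#'   `reward` (ordered by trial). Trials with `choice == "none"` must carry
#'   zero reward; they trigger no value update.
#' @param params a [model_params()].
#' @param model_kind `"context_dependent"` or `"context_free"`.
#' @param q_init `NULL` (all zeros), a scalar, or a [value_state()].
#' @return A tibble, one row per trial, with the model kind and params
#'   attached as attributes `"model_kind"` and `"params"`.
#' @export
run_trajectory <- function(data, params,
                           model_kind = c("context_dependent", "context_free"),
                           q_init = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(params, "model_params"))
  need <- c("context", "coherence", "choice", "reward")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  none <- data$choice == "none"
  if (any(none & data$reward != 0))
    stop("trials without a response cannot carry nonzero reward", call. = FALSE)
  codes <- .forward_codes(data, model_kind)
  qv <- .q_init_vector(q_init, model_kind, codes$contexts)
  fw <- .rl_forward_cpp(codes$ctx_idx, codes$choice_up,
                        as.numeric(data$reward), as.numeric(data$coherence),
                        params$beta0, params$beta1, params$alpha,
                        qv, model_kind == "context_dependent")
  # pre-choice values in the trial's own context
  row_i <- seq_len(nrow(data))
  if (model_kind == "context_dependent") {
    q_down <- fw$q_pre[cbind(row_i, 2L * codes$ctx_idx + 1L)]
    q_up <- fw$q_pre[cbind(row_i, 2L * codes$ctx_idx + 2L)]
  } else {
    q_down <- fw$q_pre[, 1L]
    q_up <- fw$q_pre[, 2L]
  }
  out <- tibble::tibble(
    trial = if ("trial" %in% names(data)) data$trial else row_i,
    run = if ("run" %in% names(data)) data$run else NA_integer_,
    context = data$context,
    q_up = q_up, q_down = q_down,
    p_up = fw$p_up,
    rpe = fw$rpe,
    bias_amount = abs(q_up - q_down),
    indecision = -params$beta0 * (q_up - q_down) / params$beta1)
  for (k in seq_along(codes$contexts)) {
    j <- if (model_kind == "context_dependent") k else 1L  # shared values
    dqk <- fw$q_pre[, 2L * (j - 1L) + 2L] - fw$q_pre[, 2L * (j - 1L) + 1L]
    out[[paste0("ip_", codes$contexts[k])]] <- -params$beta0 * dqk / params$beta1
  }
  if ("participant" %in% names(data)) out$participant <- data$participant
  attr(out, "model_kind") <- model_kind
  attr(out, "params") <- params
  out
}

#' Simulate a learning agent on a trial schedule
#'
#' For every trial the agent's choice is a Bernoulli draw from
#' [choice_probability()] given its current value state, the reward follows
#' the payoff table via [assign_outcome()], and the chosen value is updated
#' by the delta rule. The agent always responds.
#'
#' @param schedule a schedule from [build_trial_schedule()] (its attached
#'   `task_config` supplies the payoff table).
#' @param params a [model_params()].
#' @param model_kind which update rule generates behavior.
#' @param q_init `NULL` (zeros), scalar, or [value_state()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return The schedule tibble with added columns `choice`, `correct`,
#'   `reward`.
#' @export
simulate_agent <- function(schedule, params,
                           model_kind = c("context_dependent", "context_free"),
                           q_init = NULL, seed) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(params, "model_params"))
  cfg <- attr(schedule, "config")
  if (is.null(cfg) || !inherits(cfg, "task_config"))
    stop("schedule must carry a `task_config` attribute (see build_trial_schedule)",
         call. = FALSE)
  contexts <- cfg$contexts
  ctx_i <- match(schedule$context, contexts)
  n <- nrow(schedule)
  q <- .q_init_vector(q_init, model_kind, contexts)  # [ctx*2 + dir], dir 0 = down
  cd <- model_kind == "context_dependent"
  choice <- character(n)
  reward <- numeric(n)
  withr::with_seed(seed, {
    u <- runif(n)
    for (t in seq_len(n)) {
      c_t <- if (cd) ctx_i[t] else 1L
      dq <- q[2L * c_t] - q[2L * c_t - 1L]  # up - down
      p_up <- plogis(params$beta0 * dq + params$beta1 * schedule$coherence[t])
      m <- if (u[t] < p_up) "up" else "down"
      choice[t] <- m
      r <- if (m == schedule$correct_dir[t]) cfg$payoff[[schedule$context[t]]][[m]] else 0
      reward[t] <- r
      j <- 2L * c_t - 1L + (m == "up")
      q[j] <- q[j] + params$alpha * (r - q[j])
    }
  })
  out <- schedule
  out$choice <- choice
  out$correct <- choice == schedule$correct_dir
  out$reward <- reward
  attr(out, "config") <- cfg
  out
}

#' Simulate a cohort of agents
#'
#' Generates one fresh schedule and one simulated agent per participant,
#' with per-participant sub-seeds derived from the master seed.
#'
#' @param config a [task_config()].
#' @param params generating [model_params()].
#' @param model_kind generating update rule.
#' @param n_agents cohort size (default 23).
#' @param seed master seed.
#' @param q_init passed to [simulate_agent()].
#' @return A single tibble with all participants stacked (`participant`
#'   column `"p01"`, ...), config attached as attribute.
#' @export
simulate_cohort <- function(config, params,
                            model_kind = c("context_dependent", "context_free"),
                            n_agents = 23, seed, q_init = NULL) {
  model_kind <- match.arg(model_kind)
  sub <- derive_seeds(seed, 2L * n_agents)
  out <- lapply(seq_len(n_agents), function(i) {
    id <- sprintf("p%02d", i)
    sched <- build_trial_schedule(config, seed = sub[2L * i - 1L],
                                  participant_id = id)
    simulate_agent(sched, params, model_kind, q_init, seed = sub[2L * i])
  })
  out <- dplyr::bind_rows(out)
  attr(out, "config") <- config
  out
}

#' Derive independent sub-seeds from a master seed
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Split a stacked multi-participant table into a per-participant list
#'
#' @param data tibble with a `participant` column.
#' @return named list of tibbles, each carrying the original `config`
#'   attribute.
#' @export
split_participants <- function(data) {
  cfg <- attr(data, "config")
  out <- split(data, data$participant)
  lapply(out, function(d) {
    d <- tibble::as_tibble(d)
    attr(d, "config") <- cfg
    d
  })
}
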