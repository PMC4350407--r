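# Independent reference implementations, written as plain per-trial loops
# with explicit arithmetic. They deliberately avoid the package's forward
# pass so that likelihoods and trajectories are checked by a second route.

# Forward pass of the delta-rule learner: returns per-trial pre-choice Q
# (up/down in the trial's context), P(up), rpe, and the total negative
# log-likelihood of the observed choices.
oracle_forward <- function(data, beta0, beta1, alpha,
                           context_dependent = TRUE, q_init = NULL,
                           contexts = sort(unique(data$context))) {
  n_q <- if (context_dependent) 2 * length(contexts) else 2
  q <- if (is.null(q_init)) rep(0, n_q) else as.numeric(q_init)
  # layout: per context, (down, up); context-free uses slots 1:2
  n <- nrow(data)
  q_up <- q_down <- p_up <- rpe <- numeric(n)
  nll <- 0
  for (t in seq_len(n)) {
    ci <- if (context_dependent) match(data$context[t], contexts) else 1L
    qd <- q[2 * ci - 1]; qu <- q[2 * ci]
    x <- beta0 * (qu - qd) + beta1 * data$coherence[t]
    p <- 1 / (1 + exp(-x))
    q_up[t] <- qu; q_down[t] <- qd; p_up[t] <- p
    ch <- data$choice[t]
    if (ch == "none") { rpe[t] <- NA_real_; next }
    pc <- if (ch == "up") p else 1 - p
    pc <- min(max(pc, 1e-12), 1 - 1e-12)
    nll <- nll - log(pc)
    j <- if (ch == "up") 2 * ci else 2 * ci - 1
    rpe[t] <- data$reward[t] - q[j]
    q[j] <- q[j] + alpha * rpe[t]
  }
  list(q_up = q_up, q_down = q_down, p_up = p_up, rpe = rpe, nll = nll,
       q_final = q)
}

# Sample autocorrelation by the direct O(T * L) textbook definition.
oracle_acf <- function(x, max_lag) {
  x <- x - mean(x)
  c0 <- sum(x^2) / length(x)
  vapply(0:max_lag, function(k) {
    n <- length(x)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n / c0
  }, numeric(1))
}

# A random small behavioral dataset (no model behind the choices) for
# likelihood and trajectory oracle checks.
random_toy_dataset <- function(n_trials, seed, contexts = c("A", "B")) {
  withr::with_seed(seed, tibble::tibble(
    trial = seq_len(n_trials),
    context = sample(contexts, n_trials, replace = TRUE),
    coherence = sample(c(-0.64, -0.12, -0.04, 0, 0.04, 0.12, 0.64),
                       n_trials, replace = TRUE),
    choice = sample(c("up", "down"), n_trials, replace = TRUE),
    reward = sample(0:2, n_trials, replace = TRUE)))
}

# Small task for fast glmer-based tests: 70 trials over 5 runs.
small_task_config <- function() task_config(reps_per_cell = 5)

# A cohort with no context effect, no run-by-anything interaction: each
# agent has a fixed personal bias (random intercept) and responds to
# coherence only. Built from the package's own generative machinery.
simulate_null_cohort <- function(seed, n_participants = 6,
                                 config = small_task_config()) {
  seeds <- derive_seeds(seed, 2 * n_participants)
  out <- dplyr::bind_rows(lapply(seq_len(n_participants), function(i) {
    sched <- build_trial_schedule(config, seed = seeds[2 * i - 1],
                                  participant_id = sprintf("p%02d", i))
    b <- withr::with_seed(seeds[2 * i], rnorm(1, 0, 0.5))
    pars <- model_params(beta0 = 1, beta1 = 3.5, alpha = 0)
    qi <- q_init_from_intercept(b, pars, "context_free")
    simulate_agent(sched, pars, "context_free", q_init = qi,
                   seed = seeds[2 * i] + 1L)
  }))
  attr(out, "config") <- config
  out
}

group_level_params <- function() model_params(beta0 = 0.81, beta1 = 4.01, alpha = 0.02)
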