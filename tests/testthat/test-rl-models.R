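test_that("choice probability matches hand-evaluated logistic values", {
  st <- value_state("context_dependent")
  # symmetric point: no value difference, no motion signal
  expect_equal(choice_probability(st, "A", 0, model_params(2, 5, 0.1)), 0.5)
  # strong upward motion at the cohort-level estimates
  p <- choice_probability(st, "A", 0.64, model_params(0.81, 4.01, 0.02))
  expect_equal(p, 1 / (1 + exp(-4.01 * 0.64)), tolerance = 1e-12)
  expect_equal(p, 0.9286, tolerance = 1e-4)
  # pure value bias
  st2 <- value_state("context_free", q = c(down = 0, up = 1))
  p2 <- choice_probability(st2, NULL, 0, model_params(1, 0, 0))
  expect_equal(p2, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(p2, 0.7311, tolerance = 1e-4)
})

test_that("up and down probabilities are complementary and monotone", {
  withr::with_seed(99, {
    for (i in 1:25) {
      pars <- model_params(runif(1, -2, 2), runif(1, -6, 6), runif(1))
      q <- runif(4, -1, 2)
      st <- value_state("context_dependent", q = q)
      # mirrored state: swap up/down values within each context
      st_m <- value_state("context_dependent", q = q[c(2, 1, 4, 3)])
      s <- runif(1, -1, 1)
      p_up <- choice_probability(st, "A", s, pars)
      p_down <- choice_probability(st_m, "A", -s, pars)
      expect_equal(p_up + p_down, 1, tolerance = 1e-12)
    }
    # strictly increasing in S and in the value advantage of up
    pars <- model_params(1.2, 3, 0.1)
    s_grid <- seq(-1, 1, by = 0.25)
    p_s <- vapply(s_grid, function(s)
      choice_probability(value_state("context_free"), NULL, s, pars), numeric(1))
    expect_true(all(diff(p_s) > 0))
    dq_grid <- seq(-2, 2, by = 0.5)
    p_q <- vapply(dq_grid, function(d)
      choice_probability(value_state("context_free", q = c(down = 0, up = d)),
                         NULL, 0.1, pars), numeric(1))
    expect_true(all(diff(p_q) > 0))
  })
})

test_that("delta-rule updates do the arithmetic and touch only the chosen cell", {
  st <- value_state("context_dependent")
  up <- update_context_dependent(st, "A", "up", reward = 2, alpha = 0.02)
  expect_equal(up$rpe, 2)
  expect_equal(up$state[["A.up"]], 0.04)
  expect_equal(as.numeric(up$state[c("A.down", "B.down", "B.up")]), rep(0, 3))
  # zero learning rate: prediction error reported, state untouched
  z <- update_context_dependent(st, "B", "down", reward = 1, alpha = 0)
  expect_equal(z$rpe, 1)
  expect_identical(as.numeric(z$state), as.numeric(st))
  # context-free: full replacement at alpha = 1, unchosen entry untouched
  stf <- value_state("context_free", q = c(down = 0.3, up = 1))
  r <- update_context_free(stf, "up", reward = 0, alpha = 0.5)
  expect_equal(r$rpe, -1)
  expect_equal(r$state[["up"]], 0.5)
  expect_equal(r$state[["down"]], 0.3)
  r1 <- update_context_free(stf, "down", reward = 2, alpha = 1)
  expect_equal(r1$state[["down"]], 2)
  expect_error(update_context_free(stf, "down", 1, alpha = 1.5), "alpha")
  expect_error(update_context_dependent(stf, "A", "up", 1, 0.1), "context")
})

test_that("repeated constant reward follows the geometric-series closed form", {
  alpha <- 0.13; r <- 2; t_max <- 40
  st <- value_state("context_free")
  qs <- numeric(t_max)
  for (t in seq_len(t_max)) {
    st <- update_context_free(st, "up", r, alpha)$state
    qs[t] <- st[["up"]]
  }
  expect_equal(qs, r * (1 - (1 - alpha)^seq_len(t_max)), tolerance = 1e-12)
})

test_that("indecision point solves P(up) = 0.5 and matches bisection", {
  pars <- model_params(0.81, 4.01, 0.02)
  expect_equal(indecision_point(value_state("context_free"), NULL, pars), 0)
  st1 <- value_state("context_free", q = c(down = 0, up = 1))
  expect_equal(indecision_point(st1, NULL, pars), -0.81 / 4.01)
  expect_equal(indecision_point(st1, NULL, pars), -0.2020, tolerance = 1e-4)
  expect_error(indecision_point(st1, NULL, model_params(1, 0, 0.1)), "beta1")
  withr::with_seed(12, {
    for (i in 1:30) {
      pars <- model_params(runif(1, 0.1, 2), runif(1, 0.5, 6), runif(1))
      st <- value_state("context_dependent", q = runif(4, -1, 2))
      for (ctx in c("A", "B")) {
        s_star <- indecision_point(st, ctx, pars)
        root <- uniroot(function(s) choice_probability(st, ctx, s, pars) - 0.5,
                        interval = s_star + c(-2, 2), tol = 1e-12)$root
        expect_lt(abs(s_star - root), 1e-8)
      }
    }
  })
})

test_that("run_trajectory reproduces a hand-rolled per-trial loop", {
  pars <- model_params(0.9, 3.5, 0.15)
  for (seed in 1:6) {
    d <- random_toy_dataset(25, seed = seed)
    for (mk in c("context_dependent", "context_free")) {
      tr <- run_trajectory(d, pars, mk)
      or <- oracle_forward(d, pars$beta0, pars$beta1, pars$alpha,
                           context_dependent = mk == "context_dependent")
      expect_equal(tr$q_up, or$q_up, tolerance = 1e-12)
      expect_equal(tr$q_down, or$q_down, tolerance = 1e-12)
      expect_equal(tr$p_up, or$p_up, tolerance = 1e-12)
      expect_equal(tr$rpe, or$rpe, tolerance = 1e-12)
      expect_equal(tr$bias_amount, abs(or$q_up - or$q_down), tolerance = 1e-12)
    }
  }
})

test_that("trajectory invariants: flat bias without learning, context-free
           equivalence on single-context data, bounded values", {
  pars0 <- model_params(1, 4, 0)
  d <- random_toy_dataset(40, seed = 3)
  tr <- run_trajectory(d, pars0, "context_dependent",
                       q_init = value_state("context_dependent",
                                            q = c(0, 0.5, 0, 0.5)))
  expect_true(all(abs(tr$bias_amount - 0.5) < 1e-12))
  # one context only: the two update rules coincide exactly
  d1 <- random_toy_dataset(60, seed = 4, contexts = "A")
  pars <- model_params(0.8, 3, 0.2)
  t_cd <- run_trajectory(d1, pars, "context_dependent")
  t_cf <- run_trajectory(d1, pars, "context_free")
  expect_equal(t_cd$p_up, t_cf$p_up, tolerance = 1e-12)
  expect_equal(t_cd$rpe, t_cf$rpe, tolerance = 1e-12)
  # convex-combination property: Q stays inside the payoff range
  d2 <- random_toy_dataset(200, seed = 5)
  t2 <- run_trajectory(d2, model_params(1, 2, 0.7), "context_dependent")
  expect_true(all(t2$q_up >= 0 & t2$q_up <= 2))
  expect_true(all(t2$q_down >= 0 & t2$q_down <= 2))
  # inconsistent data: unanswered trial with nonzero reward
  d3 <- d2[1:5, ]; d3$choice[2] <- "none"; d3$reward[2] <- 1
  expect_error(run_trajectory(d3, pars, "context_free"), "nonzero reward")
})

test_that("simulated agents are reproducible and saturate at high coherence", {
  cfg <- task_config()
  sched <- build_trial_schedule(cfg, seed = 21)
  pars <- model_params(0.81, 50, 0)
  a <- simulate_agent(sched, pars, "context_dependent", seed = 5)
  b <- simulate_agent(sched, pars, "context_dependent", seed = 5)
  expect_identical(a, b)
  # beta1 = 50, alpha = 0: choices at |S| = 0.64 are essentially deterministic
  hi <- a[abs(a$coherence) == 0.64, ]
  expect_gte(mean(hi$correct), 0.99)
})

test_that("simulated choice frequencies match the analytic psychometric rule", {
  # alpha = 0 keeps P(up) fixed per cell; many repetitions per cell
  cfg <- task_config(reps_per_cell = 100)  # 1400 trials
  pars <- model_params(1, 3, 0)
  qi <- value_state("context_dependent", q = c(0, 0.6, 0.6, 0))  # A up, B down
  sched <- build_trial_schedule(cfg, seed = 31)
  ag <- simulate_agent(sched, pars, "context_dependent", q_init = qi, seed = 32)
  for (ctx in c("A", "B")) {
    for (s in cfg$coherence_levels) {
      cell <- ag[ag$context == ctx & ag$coherence == s, ]
      p_true <- choice_probability(qi, ctx, s, pars)
      moe <- 4 * sqrt(p_true * (1 - p_true) / nrow(cell))
      expect_lt(abs(mean(cell$choice == "up") - p_true), moe + 1e-9)
    }
  }
})

test_that("asymmetric payoffs grow the bias across the session", {
  cfg <- task_config()
  pars <- group_level_params()
  sched <- build_trial_schedule(cfg, seed = 41)
  ag <- simulate_agent(sched, pars, "context_dependent", seed = 42)
  tr <- run_trajectory(ag, pars, "context_dependent")
  expect_gt(mean(tr$bias_amount[ag$run == 5]), mean(tr$bias_amount[ag$run == 1]))
})

test_that("a practice intercept maps to the equivalent initial value shift", {
  pars <- model_params(0.8, 4, 0.02)
  qi <- q_init_from_intercept(0.4, pars, "context_dependent")
  expect_equal(qi[["A.up"]], 0.5)
  expect_equal(qi[["B.up"]], 0.5)
  expect_equal(qi[["A.down"]], 0)
  # the induced choice probability at S = 0 equals plogis(intercept)
  expect_equal(choice_probability(qi, "A", 0, pars), plogis(0.4))
  expect_error(q_init_from_intercept(0.4, model_params(0, 4, 0.1)), "beta0")
})
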