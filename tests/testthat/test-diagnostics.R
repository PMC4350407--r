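make_small_cohort <- function(n_agents = 3, seed = 400, params = group_level_params(),
                              model_kind = "context_dependent",
                              config = task_config()) {
  simulate_cohort(config, params, model_kind, n_agents = n_agents, seed = seed)
}

test_that("psychometric summary covers the full design grid", {
  coh <- make_small_cohort(n_agents = 2)
  ps <- psychometric_by_run(coh)
  expect_equal(nrow(ps), 2 * 5 * 7)  # context x run x coherence
  expect_true(all(ps$n == 2 * 4))    # 4 per cell per run per participant
  expect_true(all(ps$p_up >= 0 & ps$p_up <= 1))
})

test_that("an ideal observer saturates the psychometric extremes", {
  cfg <- task_config()
  coh <- make_small_cohort(n_agents = 2, seed = 401,
                           params = model_params(1, 50, 0))
  ps <- psychometric_by_run(coh)
  expect_true(all(ps$p_up[ps$coherence == 0.64] > 0.97))
  expect_true(all(ps$p_up[ps$coherence == -0.64] < 0.03))
})

test_that("psychometric group means ignore participant order and track the model", {
  coh <- make_small_cohort(n_agents = 4, seed = 402,
                           params = model_params(1, 3, 0))
  parts <- split_participants(coh)
  shuffled <- dplyr::bind_rows(parts[c(3, 1, 4, 2)])
  expect_equal(psychometric_by_run(coh), psychometric_by_run(shuffled))
  # with alpha = 0 the model P(up) per cell is plogis(beta1 * S) exactly;
  # observed proportions agree within binomial error (16 trials per cell
  # per run across 4 participants; 4 sd margin)
  tr <- dplyr::bind_rows(lapply(parts, run_trajectory,
                                params = model_params(1, 3, 0),
                                model_kind = "context_dependent"))
  ps <- psychometric_by_run(coh, trajectory = tr)
  expect_equal(ps$p_model, plogis(3 * ps$coherence), tolerance = 1e-10)
  moe <- 4 * sqrt(ps$p_model * (1 - ps$p_model) / ps$n)
  expect_true(all(abs(ps$p_up - ps$p_model) <= moe + 1e-9))
})

test_that("residual ACF matches the direct-definition oracle", {
  coh <- make_small_cohort(n_agents = 3, seed = 403)
  parts <- split_participants(coh)
  tr <- dplyr::bind_rows(lapply(parts, run_trajectory,
                                params = group_level_params(),
                                model_kind = "context_dependent"))
  rep <- residual_acf(coh, tr, max_lag = 15)
  expect_equal(rep$acf$acf[1], 1)               # lag 0 by definition
  expect_equal(rep$band, 1.96 / sqrt(280))
  expect_equal(rep$band, 0.1171, tolerance = 1e-3)
  # equal-weight average of per-participant sample ACFs, direct O(T*L) oracle
  d <- dplyr::left_join(coh, tr[, c("participant", "trial", "p_up")],
                        by = c("participant", "trial"))
  manual <- sapply(split(d, d$participant), function(p) {
    p <- p[order(p$trial), ]
    oracle_acf(as.integer(p$choice == "up") - p$p_up, 15)
  })
  expect_equal(rep$acf$acf, rowMeans(manual), tolerance = 1e-10)
  expect_error(residual_acf(coh, tr, max_lag = 280), "max_lag")
})

test_that("true-model residuals look white", {
  coh <- make_small_cohort(n_agents = 6, seed = 404)
  parts <- split_participants(coh)
  tr <- dplyr::bind_rows(lapply(parts, run_trajectory,
                                params = group_level_params(),
                                model_kind = "context_dependent"))
  rep <- residual_acf(coh, tr, max_lag = 20)
  inside <- abs(rep$acf_by_participant[-1, ]) <= rep$band
  expect_gte(mean(inside), 0.85)
  # the group mean is tighter still
  expect_true(all(abs(rep$acf$acf[-1]) <= rep$band))
})

test_that("indecision trajectories are flat without learning and diverge with it", {
  cfg <- task_config()
  # alpha = 0 cohort initialized with a fixed bias: flat at the implied point
  pars0 <- model_params(1, 4, 0)
  qi <- value_state("context_dependent", q = c(0, 0.4, 0, 0.4))
  seeds <- derive_seeds(405, 4)
  parts <- lapply(1:2, function(i) {
    s <- build_trial_schedule(cfg, seed = seeds[2 * i - 1],
                              participant_id = sprintf("p%02d", i))
    ag <- simulate_agent(s, pars0, "context_dependent", q_init = qi,
                         seed = seeds[2 * i])
    run_trajectory(ag, pars0, "context_dependent", q_init = qi)
  })
  flat <- indecision_trajectory_summary(dplyr::bind_rows(parts))
  expect_true(all(abs(flat$mean_ip - (-0.4 / 4)) < 1e-12))
  expect_true(all(flat$sem < 1e-12))
  # learning cohort: contexts drift apart in opposite signed directions
  coh <- make_small_cohort(n_agents = 5, seed = 406)
  tr <- dplyr::bind_rows(lapply(split_participants(coh), run_trajectory,
                                params = group_level_params(),
                                model_kind = "context_dependent"))
  s <- indecision_trajectory_summary(tr)
  gap <- function(tr_rng) {
    x <- s[s$trial %in% tr_rng, ]
    mean(x$mean_ip[x$context == "B"]) - mean(x$mean_ip[x$context == "A"])
  }
  first_run <- 1:56; last_run <- 225:280
  expect_gt(abs(gap(last_run)), abs(gap(first_run)))
  # context A favors up: its indecision point moves negative; B positive
  expect_lt(mean(s$mean_ip[s$context == "A" & s$trial %in% last_run]), 0)
  expect_gt(mean(s$mean_ip[s$context == "B" & s$trial %in% last_run]), 0)
  expect_equal(attr(s, "trials_per_run"), rep(56L, 5))
})

test_that("a single-participant cohort omits the s.e.m. band", {
  coh <- make_small_cohort(n_agents = 1, seed = 407)
  tr <- run_trajectory(coh, group_level_params(), "context_dependent")
  expect_message(s <- indecision_trajectory_summary(tr), "s.e.m.")
  expect_true(all(is.na(s$sem)))
})

test_that("diagnostic plots build without error", {
  coh <- make_small_cohort(n_agents = 2, seed = 408)
  parts <- split_participants(coh)
  tr <- dplyr::bind_rows(lapply(parts, run_trajectory,
                                params = group_level_params(),
                                model_kind = "context_dependent"))
  expect_s3_class(plot_psychometric(psychometric_by_run(coh, tr)), "ggplot")
  expect_s3_class(plot_indecision_trajectory(indecision_trajectory_summary(tr)),
                  "ggplot")
  expect_s3_class(plot_acf_report(residual_acf(coh, tr)), "ggplot")
})
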