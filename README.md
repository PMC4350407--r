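# rewardbias

Model-based behavioral analysis of **reward-induced bias acquisition in
perceptual decisions**: a simulation and estimation toolkit for the
two-context random-dot motion discrimination task with asymmetric payoffs.

When correct "up" and "down" responses pay differently — and the asymmetry
reverses between two cued reward contexts — observers gradually shift
their choices toward the better-paid direction. `rewardbias` is for
researchers who want to quantify that shift from trial-level choice data:
it simulates the task, fits trial-by-trial reinforcement-learning choice
models by maximum likelihood, compares them by group AIC and by
hierarchical logistic regression likelihood-ratio tests, tracks the bias
as the psychometric function's indecision point, checks residual
autocorrelations, and exports model-derived fMRI parametric modulators as
FSL three-column event files.

## The model

On trial *t* with signed coherence *Sₜ* (positive = upward) and reward
context *cₜ*, the probability of choosing "up" (*m₁*) is

> P(m₁) = 1 / (1 + exp{ −[ β₀ (Q(m₁) − Q(m₀)) + β₁ Sₜ ] })

and after feedback *rₜ* the chosen action's value is updated by the delta
rule with learning rate α:

* **context-dependent**: δ′ₜ = rₜ − Qₜ(mₜ | cₜ);
  Qₜ₊₁(mₜ | cₜ) = Qₜ(mₜ | cₜ) + α′ δ′ₜ
* **context-free**: δₜ = rₜ − Qₜ(mₜ);  Qₜ₊₁(mₜ) = Qₜ(mₜ) + α δₜ

The trial-wise bias is |Q(m₁|c) − Q(m₀|c)| and the indecision point —
the coherence at which both responses are equally likely — is
S\* = −β₀ (Q(m₁) − Q(m₀)) / β₁. Models are compared by group AIC,
Σₙ (2·nllₙ + 2k) with k = 3 parameters per participant.

The task: 2 reward contexts × 7 signed coherence levels
(0, ±4, ±12, ±64%) × 20 repetitions = 280 trials over 5 runs, payoffs
2/1/0 points (high-reward correct / low-reward correct / otherwise),
truncated-exponential ITIs (mean 4 s, range 2.7–12.7 s).

## Worked example

Simulate a 23-participant cohort from the context-dependent learner at
cohort-level parameters (β₀ = 0.81, β₁ = 4.01, α = 0.02), then ask which
model the data prefer:

```r
library(rewardbias)

cfg  <- task_config()
pars <- model_params(beta0 = 0.81, beta1 = 4.01, alpha = 0.02)

cohort <- simulate_cohort(cfg, pars, "context_dependent",
                          n_agents = 23, seed = 7)
cmp <- compare_models(cohort, seed = 8)
cmp
#> <cohort_comparison>
#>   context_dependent  group AIC    7170.24  better for 19 participant(s)
#>   context_free       group AIC    7290.03  better for 4 participant(s)
#>   winner: context_dependent
```

The generating (context-dependent) model wins the group AIC and fits 19
of the 23 simulated participants better. Rebuilding each participant's
value trajectory under the winning fits gives the bias-acquisition curve
and residual diagnostics:

```r
parts <- split_participants(cohort)
best  <- cmp$fits[cmp$fits$model_kind == cmp$winner, ]
traj  <- dplyr::bind_rows(lapply(parts, function(d) {
  p <- best[best$participant == d$participant[[1]], ]
  run_trajectory(d, model_params(p$beta0, p$beta1, p$alpha), cmp$winner)
}))

s <- indecision_trajectory_summary(traj)
# mean indecision point in run 5: context A -0.111, context B +0.106

residual_acf(cohort, traj)
#> <acf_report> 23 participants x 280 trials, band +/- 0.1171
#>   0 of 20 nonzero lags outside the white-noise band
```

By the final run the two contexts' indecision points have drifted apart
in opposite directions — context A (which pays "up" more) needs about 11%
*downward* coherence before the observer is indifferent, context B the
mirror image — while the residuals of the fitted model show no leftover
trial-to-trial structure. `plot_psychometric()`,
`plot_indecision_trajectory()` and `plot_acf_report()` render these
summaries; `export_all_regressors()` writes the |coherence|, bias-amount
and prediction-error modulators as mean-centered FSL event files.

A command-line pipeline over the same functions (simulate / fit /
compare / diagnose / export-regressors / recover) is in
`inst/cli/rewardbias.R`.

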