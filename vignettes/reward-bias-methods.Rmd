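---
title: "Modeling reward-induced bias acquisition in perceptual decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reward-induced bias acquisition in perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardbias)
library(dplyr)
```

## The task and the scientific question

In a two-alternative random-dot motion discrimination task, an observer
reports whether coherent motion is upward or downward. When the two
responses pay asymmetrically, observers shift their choices toward the
better-paid alternative, and the shift grows as they experience the payoffs.
`rewardbias` models that acquisition process: it simulates the task,
fits trial-by-trial learning models to choice data, quantifies the bias as
the horizontal shift of the psychometric function (the *indecision point*),
and exports the model's internal quantities as fMRI regressors.

The task crosses **two reward contexts** (cued before each trial) with
**seven signed coherence levels** (0, ±4, ±12, ±64%, represented internally
as signed proportions ±0.04, ±0.12, ±0.64). In one context a correct
"up" earns the high payoff and a correct "down" the low payoff; the other
context reverses the asymmetry. Incorrect or missing responses earn
nothing. Every (context, coherence) cell repeats 20 times, giving 280
trials spread evenly over 5 runs of 56. Trials are separated by a
truncated-exponential inter-trial interval (mean 4 s, range 2.7–12.7 s)
whose rate parameter is solved numerically at configuration time so the
truncated mean is exact. A practice session (nine coherence levels,
0, ±6, ±12, ±64, ±80%, 60 repetitions in six 90-trial blocks, no contexts)
is also generated for completeness.

### Payoff magnitudes

The point values of the payoffs are a free design choice; the defaults are
2 (high-reward correct), 1 (low-reward correct) and 0 otherwise. They keep
the learned values on an interpretable point scale while preserving the
asymmetry that drives bias, and they are fully configurable through
`task_config(payoff = ...)`.

### Randomization

Reward contexts are balanced exactly — 20 trials per (context, coherence)
cell, 4 per cell per run — so the context sequence is a balanced random
permutation within each run rather than i.i.d. draws. This is standard
counterbalancing practice; it leaves no exploitable sequential structure
(the lag-1 autocorrelation of the context sequence is the small negative
value implied by sampling without replacement, about $-1/(n-1)$ per run).
The correct direction of 0%-coherence trials is a fair seeded Bernoulli
draw per trial. Every stochastic operation takes an explicit seed and
leaves the caller's RNG state untouched.

## The learning models

On trial $t$ with signed coherence $S_t$ and reward context $c_t$, the
probability of choosing "up" ($m_1$) is a logistic in the linear
combination of the learned value difference and the stimulus:

$$
P_t(m_1) \;=\;
\frac{1}{1 + \exp\!\big\{-\big[\beta_0\,(Q_t(m_1) - Q_t(m_0)) + \beta_1 S_t\big]\big\}}
$$

so that $P(\text{up})$ rises with upward coherence and with the value
advantage of "up". (The sign convention is chosen so positive fitted
$\beta_1$ corresponds to rising psychometric curves; the equivalent form
with both signs flipped describes $P(m_0)$.)

After feedback $r_t$, the chosen action's value is updated by the delta
rule. Two hypotheses differ in what the value is conditioned on:

* **Context-dependent model** — values are kept per (context, direction):
  $\delta'_t = r_t - Q_t(m_t \mid c_t)$,
  $Q_{t+1}(m_t \mid c_t) = Q_t(m_t \mid c_t) + \alpha' \delta'_t$ (4 values).
* **Context-free model** — values ignore the context:
  $\delta_t = r_t - Q_t(m_t)$,
  $Q_{t+1}(m_t) = Q_t(m_t) + \alpha \delta_t$ (2 values).

Both models have three free parameters $\{\beta_0, \beta_1, \alpha\}$. The
prediction error $\delta$ is reported unscaled (before multiplication by
$\alpha$). Only the chosen action's value changes; values initialized
inside the payoff range stay inside it (the update is a convex
combination). With a single context the two models coincide exactly.

The **indecision point** is the coherence at which both responses are
equally likely:

$$ S^{*} = -\,\beta_0\,\big(Q(m_1) - Q(m_0)\big) / \beta_1, $$

the horizontal shift of the psychometric function. It may lie outside the
tested coherence range, and is undefined at $\beta_1 = 0$ (the package
raises an error there rather than returning an arbitrary value).

### Value initialization

Values default to zero. Observers who enter the task with a pre-existing
bias can be accommodated by `q_init_from_intercept()`: a logistic intercept
$b$ estimated from practice-session choices maps onto an initial value
difference $\Delta Q = b/\beta_0$, placed on the "up" value of every
context. No formula for this mapping is forced on the user; it is one
natural choice and any `value_state` can be supplied instead.

## Maximum-likelihood fitting and model comparison

The likelihood of a participant's choice sequence is the product over
trials of the model's probability of the chosen option; `rewardbias`
minimizes the negative log-likelihood with Nelder–Mead simplex search
(relative tolerance $10^{-10}$) from 10 seeded initializations by default
(one canonical start plus 9 random). $\alpha$ is optimized through a
logistic reparameterization to stay in $[0,1]$; $\beta_0, \beta_1$ are
unconstrained — fitted values on well-behaved data come out positive
without a constraint. Probabilities are clipped to
$[10^{-12}, 1-10^{-12}]$ inside the likelihood only, never in simulation.
The forward pass is implemented in C++ and verified in the test suite
against a plain per-trial R loop to $10^{-12}$.

Models are compared by group AIC,
$\mathrm{AIC} = \sum_n (2\,\mathrm{nll}_n + 2k)$ with $k = 3$, i.e. the
standard per-participant AIC summed over the cohort, plus per-participant
winner counts. Per-participant AIC differences below $10^{-6}$ are counted
as unresolved ties rather than assigned to either model, since any such
difference is within optimizer noise.

Degenerate regimes to be aware of: with nearly deterministic choices
(very large $\beta_1$, complete separation) the slope estimate grows
without bound — the fit still converges in likelihood but the parameter is
at a boundary in effect; and participants who never develop a bias leave
$\beta_0$ weakly identified, which inflates its dispersion across a cohort
(medians are the robust cohort summary).

## Hierarchical logistic regression

Run-by-run changes in bias and discrimination are tested with a
random-intercept logistic regression of upward choice on signed coherence
(numeric), context (binary factor), run (5-level factor, treatment
contrasts), and the context-by-run and coherence-by-run interactions, with
a per-participant random intercept (`lme4::glmer`). The marginal
likelihood integrates the intercept by adaptive Gauss–Hermite quadrature,
15 nodes by default, so deviances of nested fits are directly comparable;
the node count is configurable. Dropping either interaction frees 4
parameters, so the likelihood-ratio statistic is referred to
$\chi^2(4)$. The package checks nesting structurally and treats
coefficient magnitudes above 30 log-odds units as evidence of complete
separation.

Coherence enters as a single numeric covariate — the same coding the
learning model uses — rather than a factor; this is the parsimonious
choice and matches the 4-df interaction structure.

## Diagnostics

* `psychometric_by_run()` tabulates observed choice proportions per
  (context, run, coherence) cell, with across-participant s.e.m., and
  averages model-predicted probabilities over the same cells.
* `indecision_trajectory_summary()` tracks the group mean ± s.e.m. of the
  per-trial indecision point of each context — the bias-acquisition curve.
  With opposite payoff asymmetries the two curves diverge in opposite
  signed directions across runs.
* `residual_acf()` computes per-participant sample autocorrelations of the
  residuals `choice − P(up)` under a fitted model (the standard
  mean-centered, lag-0-normalized estimator), averages them with equal
  weights, and draws the white-noise 95% band $\pm 1.96/\sqrt{T}$. A
  correctly specified model leaves residuals inside the band at (almost
  all) nonzero lags; systematic choice- or stimulus-sequence effects the
  model ignores would show up as excursions. The default maximum lag is
  20 — far enough to see slow structure, short relative to $T = 280$.

## fMRI parametric modulators

`build_modulator_series()` turns model quantities into event-file
regressors with the event windows of the task: |coherence| over the 0.2-s
stimulus, the trial-wise bias amount $|Q(m_1|c_t) - Q(m_0|c_t)|$ from cue
onset to stimulus offset (1.2 s), and signed or unsigned prediction error
over the 1.5-s feedback. "Trial onset" for the bias modulator is taken as
cue onset, the first event of a trial. Weights are mean-centered within
run, since first-level GLMs are estimated per run (whole-session centering
is available). `export_fsl_events()` writes FSL three-column files at
6-decimal precision; construction is a pure function of its inputs, so
identical inputs give byte-identical files. HRF convolution, motion
confounds, and GLM estimation belong to the imaging software and are out
of scope, as is reaction-time modeling throughout the package (the data
model records no RTs, so the exported response boxcar spans the response
window rather than ending at a key press).

## Simulation-based validation

What the generator emulates: the task's exact cell balance, its ITI
distribution and event timing, asymmetric payoffs, and choice behavior
generated by the learning models themselves. What it does not emulate:
reaction times, response omissions (the data model supports them; the
generative agents always respond, since no omission model is specified),
perceptual-learning changes in discrimination, and any within-trial
evidence-accumulation dynamics. Passing tests therefore validate the
estimation machinery on data that obey the model, not the model's adequacy
for any particular empirical dataset.

The test suite runs, at the task's own dimensions:

* **Parameter recovery** — 23 agents × 280 trials simulated from the
  context-dependent model at cohort-level generating values
  ($\beta_0 = 0.81$, $\alpha = 0.02$, $\beta_1 = 4.01$); cohort medians
  must land inside plausibility bands (e.g. median $\hat\alpha$ in
  $[0.009, 0.03]$, $\hat\beta_0$ and $\hat\beta_1$ within ±50%).
* **Model recovery** — 20 replicate 23-agent cohorts per generating model;
  the generating model must win the group AIC in at least 18, in both
  directions.

A caveat the recovery experiments themselves expose: at 280 trials and
$\alpha = 0.02$ the likelihood is nearly flat in $\alpha$ (a profile grid
changes the NLL by only a few tenths over $\alpha \in [0.005, 0.1]$), and
$\beta_0$ and $\alpha$ trade off along a ridge — a faster learner with a
weaker value weight produces almost the same choices. Per-participant
estimates of these two parameters are therefore widely dispersed (single
fits at ten times the trials recover the truth closely, so this is an
information limit, not an optimizer failure), and the *cohort median*
itself varies substantially between replicate cohorts. Model recovery is
likewise asymmetric: context-dependent cohorts are identified essentially
always, while on context-free data the context-dependent model — with the
same parameter count — attains nearly the same likelihood, leaving only a
small AIC margin, so the context-free model wins most but not almost all
replicate cohorts. Both effects are properties of the design at this
trial count, and both recovery tests run at the strict bands regardless.
* **Residual whiteness** — residuals of the generating model on a
  10-agent cohort keep at least 85% of lags 1–20 inside the
  $\pm 1.96/\sqrt{280}$ band.
* **LRT calibration** — 500 null cohorts of 6 participants × 70 trials
  (a scaled-down design with the same 5-run structure: each cell once per
  run) with a participant-level random bias and no context effect; the
  context-by-run LRT must reject at the nominal 5% rate within a 99%
  binomial margin. These replications use the Laplace approximation
  (`nagq = 1`): on these designs the deviance *difference* agrees with
  15-node quadrature to three decimals, and only the difference enters
  the statistic.

Recovery fits use the default 10 restarts; a profile-likelihood check in
development confirmed the restarts re-find the global optimum on these
surfaces (the fixed-point test asserts this property directly).

## A worked example

```{r example, eval = FALSE}
cfg <- task_config()
pars <- model_params(beta0 = 0.81, beta1 = 4.01, alpha = 0.02)

cohort <- simulate_cohort(cfg, pars, "context_dependent",
                          n_agents = 23, seed = 7)
cmp <- compare_models(cohort, seed = 8)
cmp  # group AICs, per-participant winner counts, winning model

parts <- split_participants(cohort)
best <- cmp$fits |> filter(model_kind == cmp$winner)
traj <- bind_rows(lapply(seq_along(parts), function(i) {
  p <- best[best$participant == names(parts)[i], ]
  run_trajectory(parts[[i]], model_params(p$beta0, p$beta1, p$alpha),
                 cmp$winner)
}))

plot_psychometric(psychometric_by_run(cohort, traj))
plot_indecision_trajectory(indecision_trajectory_summary(traj))
plot_acf_report(residual_acf(cohort, traj))

export_all_regressors(parts[[1]],
                      traj[traj$participant == "p01", ],
                      "regressors/p01")
```

## Known limitations

* The models describe choices only; datasets with reaction times need a
  sequential-sampling treatment the package deliberately does not attempt.
* Group AIC assumes independent participants and equal $k$; it compares
  these two models, not arbitrary model families.
* The random-intercept logistic regression has no random slopes; strong
  participant heterogeneity in discrimination would call for a richer
  random-effects structure.
* Fitted $\beta_0$ and $\alpha$ are weakly identified at a few hundred
  trials (flat/ridged likelihood, above); interpret per-participant
  estimates with the cohort distribution in mind, and prefer the
  trajectory-level quantities (bias amount, indecision point), which are
  far more stable than the raw parameters that generate them.
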