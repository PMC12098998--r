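---
title: "Modelling active avoidance under prior beliefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling active avoidance under prior beliefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidprior)
library(dplyr)
```

## The behavioural problem

In active-avoidance decisions an agent can either accept a sure (or certain
enough) outcome, or pay a cost for an action that *might* avert it. The two
task framings implemented here put the same arithmetic in opposite affective
clothing. In the **robber** task the agent holds an offer `o` (a tip earned
during a shift) and meets a robber: handing the money over yields utility 0,
while fighting costs `c` and succeeds with a stimulus-specific probability
`p`, returning `o - c` on success and `-c` on failure. In the **factory**
task the agent faces a sure loss `-o` (a machine breaking down) and may pay
`c` for a repair attempt that, if it fails, still forfeits the machine:
passivity yields `-o`, action yields `-c` on success and `-o - c` on
failure.

Costs are built as a fixed component plus a percentage of the offer — robber
regimes (10, 15%), (40, 5%), (75, 0%); factory regimes (0, 10%), (50, 5%),
(100, 0%) — so that for most of the 20 offers x 3 regimes = 60 combinations
the two options' expected values sit close together and choices are
diagnostic of the agent's *belief* about `p`. The 20 offers are
`50 / (0.10, 0.15, ..., 0.95, 1, 2)` rounded to whole points; twelve
stimuli carry success probabilities on the equidistant grid `k/13`,
`k = 1..12` (7.69% to 92.31%), and are encountered in consecutive runs of
4–8 trials (multiset `{4,4,4,4,4,4,5,5,5,6,7,8}`).

## The choice models

All models share the softmax choice function
`P(go) = 1 / (1 + exp(-(Q(go) - Q(ng)) / tau))` and differ in how they value
the active option:

* **softmax_only** — assumes actions always succeed: `Q(go) = o - c`
  (robber) or `-c` (factory).
* **wsls** — the same utilities plus win-stay/lose-shift bonuses
  `+ success[t-1] * gamma+ - loss[t-1] * gamma-` keyed to the previous
  trial's outcome regardless of stimulus (flags reset at block boundaries).
* **static_prob** — a single subjective success probability `p` applied to
  every stimulus: `Q(go) = -c + p * o` (robber), `-c - (1 - p) * o`
  (factory).
* **bayes** — a beta-Bernoulli learner. The agent starts every stimulus
  from a beta prior parameterised by its mean `mu0` and *relative* variance
  `sigma0sq` (variance divided by its ceiling `mu0 * (1 - mu0)`), converted
  to shapes `alpha0 = mu0 (1/sigma0sq - 1)`,
  `beta0 = (1 - mu0)(1/sigma0sq - 1)`. Active choices increment `alpha`
  (success) or `beta` (failure); passive choices are uninformative and
  leave the belief untouched. The posterior mean `alpha / (alpha + beta)`
  replaces `p` in the static utilities.
* **bayes_between_stim** — the same learner but carrying one running
  posterior across stimuli within a block, testing whether updating is
  stimulus-bound.
* **`*_bias` variants** — an action-bias (lapse) parameter `phi` in
  (-1, 1) mixes a fixed tendency into the choice:
  `P(go) = [phi]+ + (1 - |phi|) * softmax`. Negative `phi` is a passivity
  bias, positive an action bias.
* **joint_1prior / joint_2prior** — fit both tasks at once with
  task-specific temperatures (`tau_R`, `tau_F`) and an action bias in the
  factory task only (where passivity biases are behaviourally plausible:
  the sure loss invites disengagement); the 1-prior version shares
  (`mu0`, `sigma0sq`) across tasks, the 2-prior version estimates them per
  task. Comparing the two asks whether the prior is a task-general trait.

### Parameter transforms and priors

Fitting happens in an unconstrained space where every parameter carries a
zero-centred Gaussian prior with variance 6.25. Positive parameters are
exponentiated; the temperature is additionally scaled by 0.01
(`tau = 0.01 * exp(theta)`) so that small temperatures — which matter, the
utilities being tens to hundreds of points — are well covered by the prior.
Unit-interval parameters use the logistic; `phi` uses `2 * logistic - 1`, a
symmetric, zero-centred map onto (-1, 1) (the support is stated but no
transform is canonical; this choice keeps `phi = 0` at the prior mode).

### Smoothing the rectifier

The lapse mixture involves `[phi]+` and `|phi|`, whose gradients are
undefined at zero. For gradient-based optimisation the rectifier is
replaced by a SoftPlus surrogate `log(1 + exp(100 * phi)) / 100`, and
`|phi|` analogously by `softplus(phi) + softplus(-phi)`, keeping the
likelihood differentiable everywhere. At sharpness 100 the surrogate
deviates from the exact rectifier by at most `log(2)/100 ~ 0.007` anywhere,
and the gap shrinks monotonically as the sharpness grows (both properties
are asserted in the test suite). Simulation defaults to the exact
rectifier; fitting defaults to the surrogate.

### Numerical conventions

Choice probabilities are clipped to `[1e-12, 1 - 1e-12]` before taking
logs, in both the likelihood evaluator and the simulator, so likelihoods
stay finite under extreme parameters and the two code paths agree exactly.
Belief states and outcome-history flags reset at block boundaries (new
stimuli, new schedule) and, for the base learner, with each new stimulus;
in joint fits nothing is carried across the task boundary.

## Estimation

`fit_subject_map()` minimises the penalised negative log-likelihood
`NLL(theta) + 0.5 * sum((theta - m)^2 / v)` with BFGS from 10 seeded
restarts drawn from N(0, 1) (plus the prior mean; Nelder-Mead is the
fallback if a start fails), a hedge against the multimodality the lapse
models introduce. Because the temperature spans orders of magnitude
(`tau = 0.01 * exp(theta)`) and its likelihood is a flat plateau below the
scale of the utilities, the temperature coordinate of the restarts is
additionally offset over the decades {0, 2, 4, 6}; without this, fits of
noisy agents strand on the deterministic plateau and shrinkage behaves
non-monotonically. The Laplace approximation turns the optimum into a log
model evidence,

```
log E = log L(theta*) + log N(theta* | m, v) + (d/2) log 2*pi - (1/2) log det H,
```

with `H` the Hessian of the negative log-posterior by central finite
differences (step 1e-4), eigenvalue-floored at 1e-8 before the
log-determinant. On data whose likelihood is flat the posterior is exactly
Gaussian and this expression is exact — one of the closed-form checks in
the tests.

`hierarchical_refit()` adds a self-contained empirical-Bayes group layer
with the structure of hierarchical Bayesian inference over models and
parameters: per-subject model responsibilities from the Laplace evidences,
responsibility-weighted group means and variances, and subject refits
under the updated Gaussian prior, iterated until group means move less
than 1e-4 or 50 rounds. The group variance combines the spread of the MAP
estimates with the subjects' own posterior variances (inverse Hessian
diagonals) — the fixed point of the Laplace-surrogate update — and is
floored at 1e-4; using the MAP spread alone collapses the prior whenever a
parameter is weakly identified. The reported `total_evidence` trace is the
cohort's model-marginalised evidence; it is only approximately monotone,
because the Laplace evidence over-estimates on plateaued likelihoods in
the first round and regularised refits then correct it downward. The
scheme is deliberately *not* a re-derivation of any particular toolbox's
algorithm — the aim is a transparent, testable analogue with the same
regularising behaviour.

Goodness of fit is summarised by pseudo-r² = `1 - LL / (n * ln 0.5)`: 0 at
chance, 1 at perfect prediction, negative below chance; cohort summaries
report its 25th/50th/75th percentiles.

## Model comparison

`rfx_bms()` treats each subject's best model as a random effect:
frequencies `r ~ Dirichlet(1, ..., 1)` updated variationally, exceedance
probabilities by 1e5 seeded Monte-Carlo draws from the Dirichlet posterior
(Monte-Carlo uniformly for any K, rather than the closed-form Beta special
case at K = 2, so the code path is single), and the Bayes omnibus risk from
the free-energy comparison of the random-effects model against the
equal-frequency null. The protected exceedance probability
`PXP = (1 - BOR) * XP + BOR / K` is the selection criterion: it collapses
to chance when the evidence cannot distinguish model frequencies, as the
exchangeability tests assert.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` reproduces the generative structure of the experiment:
seeded 60-trial schedules per subject, outcomes drawn only on active
choices, models drawn from a mixture, unconstrained parameters from group
Gaussians. Defaults are mean 0, SD 1 — well inside the fitting prior and
producing moderate, identifiable behaviour. Note what this implies: with
`tau = 0.01 * exp(N(0, 1))` the typical simulated agent is close to
deterministic given its beliefs, so recovery results characterise the
information content of the *design* (which choices pin down the prior)
more than robustness to decision noise. Real participants additionally
exhibit drifting attention, within-block learning-to-learn, and
response-time structure that no model here generates; passing recovery
tests therefore certifies the estimation machinery, not the empirical
adequacy of any model.

Recovery harnesses default to desk scale — 50 subjects x 240 trials x 20
repeats for model recovery, 100 subjects for parameter recovery — sizes
chosen so a full run completes comfortably in minutes on one core while
leaving Monte-Carlo error small enough for the 90%-selection and 0.7-
correlation checks. `power_simulation()` exposes the mixture, group
moments, sample-size grid and repeat count so a full-scale power analysis
(hundreds of subjects, 1000 repeats) can be run when wanted; generating
group parameters for such an analysis are study-specific inputs, so they
are configuration, not constants.

## Open choices made here

* **Counterbalanced encounter lists.** The run-length multiset is split
  into two lists balanced by total; the text fixes no composition, so the
  shipped constant is A = {4,4,4,5,5,8}, B = {4,4,4,5,6,7} (both sum 30),
  shuffled within lists and concatenated A then B. Any equal-sum partition
  would satisfy the stated intent.
* **Rounding.** Offers (and costs, for display realism — participants see
  integer points) round half-up, so 62.5 -> 63 rather than banker's
  rounding.
* **WSLS flag scope.** The outcome flags are stimulus-independent and
  refer to the immediately preceding trial, resetting at block boundaries.
* **Practice blocks** use four dedicated stimuli (ids 101-104) with counts
  {4,4,4,6} and success probabilities {0.8, 0.2, 0.5, 0.5}; they never
  reappear in main blocks.
* **ICC(2,1)** (two-way random effects, absolute agreement, single
  measure) is computed from the ANOVA mean squares with the F-based
  confidence interval, and is meant to be applied to *unconstrained*
  parameter estimates, whose Gaussian prior makes approximate normality a
  reasonable working assumption. Permutation p-values use the add-one
  correction, so p is never exactly zero.

## Known limitations

* The empirical-Bayes group step is a simplification: it propagates point
  (MAP) estimates, not full subject-level posteriors, into the group
  moments, and its evidence is Laplace-approximate throughout.
* The variational Dirichlet posterior in `rfx_bms()` is itself an
  approximation; its exceedance probabilities can deviate from the exact
  mixture posterior for very small cohorts with weak evidence differences.
* A stimulus-specific reinforcement-learning variant is deliberately out
  of scope: with 4–8 encounters per stimulus such models are not
  identifiable in this design.
* Temperature recovery is poor in the near-deterministic default regime —
  expected, since a deterministic choice sequence is compatible with any
  sufficiently small `tau`.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(20, c(bayes = 1))
cohort <- simulate_cohort(cfg, seed = 1, n_blocks = 2)
fits <- fit_cohort(cohort$data, c("bayes", "static_prob", "softmax_only"))
bms <- rfx_bms(log_evidence_matrix(fits), seed = 2)
tidy(bms)
autoplot(bms)
plot_choice_curves(cohort$data)
```
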