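---
title: "Modeling goal-directed and habitual choice in the two-stage task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling goal-directed and habitual choice in the two-stage task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
library(dplyr)
```

## The scientific problem

Human choice is driven by two interacting systems: a *model-free* (habitual)
system that caches values of actions reinforced in the past, and a
*model-based* (goal-directed) system that prospectively evaluates actions
using knowledge of the environment's structure. The two-stage Markov task
dissociates them behaviorally. A first-stage choice leads to one of two
second-stage states through fixed, instructed transition probabilities
(common 70%, rare 30%); second-stage options pay a unit reward with slowly
drifting probabilities, so subjects must keep learning throughout.

The two systems make distinct predictions for *stay behavior* — the
probability of repeating the previous first-stage choice:

- a model-free learner repeats rewarded actions regardless of how the reward
  came about: a **main effect of previous reward**;
- a model-based learner credits the reward to the second-stage state and
  chooses the first-stage action most likely to reach it again: an
  **interaction of previous transition type and previous reward** (stay after
  common-rewarded and rare-unrewarded trials, switch otherwise).

`twostepr` implements the complete computational pipeline around this logic:
the task environment, the hybrid agent, maximum-likelihood fitting, the
stay-probability read-outs, and synthetic-cohort generation with parameter
recovery as the end-to-end validation.

## The hybrid model

Second-stage model-free values follow a delta rule,
$$Q_2(s_2, a_2) \leftarrow Q_2(s_2, a_2) + \alpha_2\,\big(r - Q_2(s_2, a_2)\big),$$
and first-stage values are updated toward the (pre-update) second-stage value
of the chosen option, with an eligibility trace passing the second-stage
reward prediction error back within the trial:
$$Q_1(a_1) \leftarrow Q_1(a_1) + \alpha_1\,\big(Q_2(s_2, a_2) - Q_1(a_1)\big)
  + \alpha_1 \lambda\,\big(r - Q_2(s_2, a_2)\big).$$
Traces do not persist across trials because the drifting reward
probabilities make old credit assignments stale. Two conventions here were
genuinely open and are worth stating:

- *Update ordering.* Both first-stage correction terms use the second-stage
  value **before** its within-trial update; the update equations index all
  right-hand quantities at trial $t$, and we implement them literally.
- *Eligibility coefficient.* The trace term carries $\alpha_1 \lambda$ (not
  $\alpha_2 \lambda$). Antecedent implementations in the literature differ on
  this point; we follow the printed equations.

Model-based values apply the Bellman equation to the known transition
matrix,
$$Q^{MB}(a) = 0.7 \max_{a'} Q_2(\mathrm{common}(a), a') +
             0.3 \max_{a'} Q_2(\mathrm{other}(a), a'),$$
with no transition learning: subjects are instructed about, and practice,
the transition structure, so the agent knows it too. The first-stage net
value is the mixture $Q^{net} = \omega Q^{MB} + (1-\omega) Q^{MF}$ and
choices follow a softmax with inverse temperature $\beta_1$ plus a
perseveration bonus $\pi$ for repeating the previous first-stage action
(zero for both actions on the first trial, retained across aborted trials —
perseveration is a choice-history effect, and an aborted trial records no
new choice). At the second stage the net value equals the model-free value
and the softmax uses $\beta_2$.

### Parameters at a glance

| parameter | meaning | range | preset medians (younger/older, narrow) |
|---|---|---|---|
| $\alpha_1,\alpha_2$ | learning rates, stages 1/2 | $[0,1]$ | 0.63, 0.49 / 0.65, 0.33 |
| $\beta_1,\beta_2$ | inverse temperatures | $\ge 0$ | 3.91, 4.71 / 5.83, 2.92 |
| $\lambda$ | eligibility-trace weight | $[0,1]$ | 0.23 / 0.33 |
| $\pi$ | perseveration bonus | unbounded | 0.21 / 0.18 |
| $\omega$ | model-based weight | $[0,1]$ | 0.57 / 0.24 |

Rewards are coded 0/1 inside the model; the 10-cent magnitude enters only
the payoff accounting (`mean_payoff()`). This keeps the β scales
commensurate with the published estimates (up to ≈13.5). All Q values start
at 0.5, the midpoint of the unit reward and the center of the narrow walk
range; the initialization is configurable, and initialization-independent
properties are tested at 0 as well.

## The task environment

Reward probabilities for the four second-stage options drift as independent
Gaussian random walks (step sd 0.025 per trial) inside reflecting
boundaries: 0.25–0.75 in the narrow condition, 0.00–1.00 in the wide one.
"Reflecting" is implemented as mirror reflection ($p' = 2b - p$ for an
overflow past boundary $b$, re-applied until in range), which preserves the
step-size distribution near the bounds — clipping would pile probability
mass onto the boundary and shrink effective step sizes there. Walk starting
points are not part of the published design; the default draws them
uniformly within the bounds (seedable), and fixed starts are available for
tests. The four walks are mutually independent, matching the reference
design this task family adapts.

```{r walks, fig.width = 6, fig.height = 3}
plot_trajectory(generate_walks(random_walk_config("narrow"), 201, seed = 1))
```

Response deadlines are not simulated — synthetic agents always respond —
but the session schema carries an `aborted` flag and per-field missingness
so that real logs (where no response within 2 s aborts the trial) parse and
analyze correctly: aborted trials contribute no likelihood terms, no value
updates, and stay-probability pairs straddling them are dropped entirely
rather than spliced (a conservative choice; splicing would count a "stay"
across an unmodeled gap).

## Fitting

`negative_log_likelihood()` deterministically replays a session,
accumulating $-\log P$ of each observed choice under the model and applying
the updates with the observed outcomes. The replay is implemented in C++
(it is evaluated tens of thousands of times per fit) and is verified in the
test suite against an independently coded plain-R replay to $10^{-10}$, and
against closed forms: with $\beta_1 = \beta_2 = 0$ the likelihood is exactly
$2T\ln 2$ for $T$ completed trials.

Estimation mirrors the two-phase procedure used with human data: a coarse
grid search, then bounded local refinement (L-BFGS-B, at most 500 iterations
per start) from the twelve best grid points. Decisions within this scheme:

- *Grid traversal.* "Iterating all parameters" is ambiguous between
  coordinate-wise and factorial sweeps; the default is a full-factorial grid
  — reproducible and seed-free — deterministically thinned (longest value
  lists halved first) to at most $10^5$ points, which resolves the default
  grid to 62,500 points. A coordinate-descent mode is available
  (`grid_search(..., method = "coordinate")`).
- *Start pooling.* Starts are taken per condition from that condition's own
  grid by default (no cross-talk between conditions);
  `fit_subject(..., pool_starts = TRUE)` pools the two conditions' candidate
  lists, for fidelity with the original description.
- *Bounds.* $\alpha$'s, $\lambda$, $\omega \in [0,1]$ by definition;
  $\beta$'s bounded in $[0, 20]$ and $\pi$ in $[-5, 5]$, comfortably
  containing all published percentile ranges.
- Reported negative log-likelihoods are per condition (one 201-trial
  session), matching per-range, per-subject estimation.

## Synthetic cohorts and what they do (not) show

No trial-level human data were deposited, so the verification surface is
synthetic: `group_spec()` draws each parameter independently from a normal
distribution truncated to its bounds, with means anchored at the published
group medians (`agent_presets()`). Only medians and quartiles were reported
— no parameter covariances are recoverable — so independent draws are the
honest default; the default sds were chosen once so that typical draws
roughly span the published interquartile ranges (≈ IQR/1.35 before
truncation: 0.2 for the unit-interval learning parameters, 2.5 and 1.5 for
$\beta_1$ and $\beta_2$, 0.25 for $\lambda$, 0.12 for $\pi$, 0.2 for
$\omega$). Setting an sd to 0 fixes a parameter; `Inf` draws it uniformly
over its bounds (used for the ω-recovery experiment). Walks are seeded
independently per subject and condition; a yoked mode shares trajectories
across subjects for variance-reduction experiments.

Parameter recovery (`parameter_recovery()`) closes the loop: simulate a
cohort at known parameters, refit every session, and correlate truth with
estimates. Each subject contributes two sessions (narrow and wide, 201
trials each); since recovery is a per-subject question while fitting is per
condition, the recovered value is the mean of the two condition estimates,
which halves estimator noise without touching the fitting procedure. At
these problem sizes (50 subjects, 402 trials each, 62,500-point grid and 12
starts per session) the ω correlation exceeds 0.7 with median absolute error
below 0.2, and endpoint cohorts (ω = 0 vs ω = 1) separate cleanly — the test
suite computes these quantities rather than this vignette asserting them.

What passing these tests shows: the pipeline is internally consistent — the
likelihood is correct, the optimizer finds generating parameters, the
difference scores read out ω as intended. What it does not show: that human
data satisfy the model's assumptions. Synthetic agents have stationary
parameters, no lapses or attention drifts, no response deadlines, no
session-order or carry-over effects, and parameters drawn independently —
all of which real cohorts violate to some degree. Directional group
contrasts on synthetic "younger-like" vs "older-like" cohorts are
consistency checks of the analysis chain, not re-demonstrations of the
empirical age effect.

## Numerical choices and degenerate inputs

- Choice probabilities are computed through the stable two-option logistic
  form (`log1p(exp(·))`), so extreme $\beta$ values cannot overflow.
- With unit rewards and Q initialized in $[0,1]$, every update is a convex
  combination, so Q values remain in $[0,1]$; this is asserted
  property-style over simulated sessions.
- A session must contain at least one completed trial to have a likelihood,
  and at least two for a stay table; zero-count stay cells propagate `NA`
  rather than 0 (a 0 would bias the difference scores).
- Optimizer failures on individual starts fall back to the start's own
  likelihood and are flagged through `converged = FALSE` if no start
  succeeds; ties in the grid ranking are broken by the grid's expansion
  order, which is deterministic.
- One-trial sessions fit without error (the estimate is of course
  uninformative; the likelihood at symmetric initial values is exactly
  $2\ln 2$ regardless of most parameters).

## Problem sizes

The shipped experiments use 201 trials per condition (the study design),
200 simulated subjects per endpoint for the ω signatures, 50 subjects for
ω recovery, and 30 subjects per group for the cohort contrast — sizes at
which the Monte-Carlo error of every asserted quantity is well inside its
acceptance margin, while a full test run stays in the minutes range on a
single CPU.

## Known limitations

- No hierarchical or Bayesian estimation; per-session ML only, with no
  standard errors on parameters.
- No transition-probability learning, forgetting of unchosen options, or
  separate reward sensitivities — the model space is exactly the
  seven-parameter hybrid.
- Inferential group statistics on human cohorts (repeated-measures ANOVA,
  mixed-effects logistic regressions) are out of scope; `cohort_summary()`
  provides descriptive means and standard errors only.
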