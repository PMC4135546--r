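---
title: "An actor-critic model of signaled lever-press avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An actor-critic model of signaled lever-press avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidrl)
```

## The task and the model

`avoidrl` simulates discriminated lever-press avoidance, the operant
paradigm in which a warning tone precedes footshock and a lever-press
during the warning period cancels the shock (an *avoidance* response),
while a press during the shock period terminates it (an *escape*
response). Time is discretized into 10-s steps. A standard trial is 54
steps: 6 warning-only steps, 30 shock-period steps, and 18 steps of a
signaled inter-trial interval (ITI). Twenty trials make a session,
preceded by a 6-step stimulus-free pre-period in the chamber (presses
there are *anticipatory* responses); 12 acquisition sessions are followed
by 12 extinction sessions in which shock is never delivered. Between
consecutive sessions the animal sits in its home cage for 18 000 steps
(48 h at 10 s per step is 17 280; the schedule uses the round 18 000
preset), during which the lever is unavailable.

The agent is a linear actor-critic learner over a 5-unit binary input
vector: warning signal `W`, safety/ITI signal `S`, shock `U`, and a
one-hot context pair (experimental chamber vs home cage). At every
timestep the actor computes a value for each of `A = 100` candidate
actions (one arbitrarily designated lever-press, the rest standing for
grooming, rearing, and so on):

$$M_a = \sum_i \left( m[a][i]\, I_i + P\, c[a][i] \right)$$

and samples one by softmax, $\Pr(r) \propto e^{M_r/T}$, where $T$ is the
explore/exploit temperature. $c$ is a perseveration trace (a choice
kernel): the executed action's trace is refreshed to 1 and every other
action's trace decays by 0.95 per step, so recently emitted behaviors are
repeated regardless of their outcomes, with strength set by the
perseveration weight $P$.

Reinforcement is $R_{\text{shock}} = -4$ when shock is present at the
next step (the rule looks one step ahead, so a press that removes the
upcoming shock avoids the penalty), else $R_{\text{press}} = -0.2$ for a
lever-press, else 0. A linear critic predicts discounted reinforcement,
$V = \sum_i v[i] I_i$, and the temporal-difference error

$$\delta = R + 0.9\,V_{t+1} - V_t$$

trains both modules: $\Delta v[i] = \alpha\,\delta\,I_i$ (clipped at
$\pm|R_{\text{shock}}|$) and, for the executed action only,
$\Delta m[r][i] = \varepsilon\,(\delta - m[r][i])\,I_i$ with $m \ge 0$.

## Strain presets

Two parameter presets reproduce the two rat strains the model targets:

| parameter | SD (outbred control) | WKY (behaviorally inhibited) |
|---|---|---|
| critic learning rate $\alpha$ | 0.05 | 0.005 |
| actor learning rate $\varepsilon$ | 0.005 | 0.005 |
| temperature $T$ | 1.0 | 0.25 |
| perseveration $P$ | 0.25 | 0 |

The three altered WKY values map onto the strain's phenotype: a lower
$T$ (less exploration) accelerates acquisition, a lower $\alpha$ slows
the critic's re-learning and therefore extinction, and $P = 0$ removes
the warm-up effect (below). All other parameters are shared.

```{r presets}
strain_preset("WKY")$params
```

## Warm-up

The package's central phenomenon is *warm-up*: transiently reduced
avoidance on the first trial(s) of a session relative to the end of the
previous session. In the model it arises purely from the perseveration
trace. During the long home-cage period the agent keeps emitting
(non-lever) behaviors; the most recent ones carry traces into the next
session and bias the first trials toward repeating them, while the
lever — unavailable between sessions — has lost its own trace. Both
effects dissipate within a trial or two as the lever is re-emitted.
Because the trace term is deliberately *not* gated by the current inputs,
traces acquired in the home-cage context still act after the context
switches to the chamber; this design choice (the formula's one genuine
ambiguity) is what lets warm-up survive round-the-clock housing, where
the context never changes. The alternative reading — refreshing traces
only for inputs active at execution time — is available via
`model_params(trace_gated = TRUE)`.

The warm-up score of a cohort is the across-run mean of
`avoid(trial 2) - avoid(trial 1)` averaged over sessions 10-12 (the last
acquisition block); `warmup_score()` also implements the block-edge
variant used in empirical within-session analyses (last two trials of
the preceding session vs first two of the window).

A note on effect size: with the SD preset the score is reliably positive
but modest. Averaged over 40 replicate runs the score is about
0.10-0.17 under the standard 48-h interval, a 30-min interval,
round-the-clock housing, and during early extinction, and about zero for
continuous sessions and for WKY under every interval — the qualitative
pattern of the phenomenon, uniformly. At the canonical cohort size of 10
runs the across-run standard error is about 0.1, so any single 10-run
cohort may fail to clear a two-standard-error bound in a given
condition; the dissociation tests in `tests/testthat/test-acceptance.R`
apply that bound anyway and a few of them are expected to sit at the
edge of it. Increase `n_runs` in `run_cohort()` when a tighter estimate
of the score is needed.

## The event stream and learning step

One learning step spans one timestep: observe inputs $I_t$, compute
action values, sample an action, let the environment apply its
consequences (a press during warning or shock truncates that period and
jumps to the ITI at the next step), evaluate $R$ against the
post-transition state, compute $\delta$ with $V_{t+1}$ from the new
inputs and $V_t$ stored from the previous step, and update critic and
actor with the *pre*-transition inputs (standard TD(0) credit
assignment; the formulas' "current input" is ambiguous between the two
conventions). The stream is continuous across trials, sessions, and
inter-session periods, so value expectations also relax during the
home-cage period and the context switches produce their own prediction
errors. At the very end of the experiment, where no next state exists,
the home-cage inputs stand in as the post-transition state (the animal
is removed from the chamber).

Trials are scored by the first press: before `warning_len` steps it is
an avoidance, before `warning_len + shock_len` an escape, later (or
never) neither; latency is counted in steps from warning onset and
defaults to the full 54-step trial when no press occurs. Extinction
trials keep the warning signal on through the whole would-be shock
period, so the timeline is identical except that `U` never appears.

## Two engines, one arithmetic

`run_experiment()` has two interchangeable engines. The reference engine
is written in plain R directly from the update rules above
(`run_trial()`, `run_session()`, `run_intersession()` are its exposed
pieces, and accept scripted policies for environment tests). The
compiled engine (Rcpp) executes the identical sequence of floating-point
operations — same accumulation order, the same extended-precision sums R
uses internally, one uniform draw per timestep — so the two produce
bitwise-identical trajectories from the same seed; the test suite
asserts exact equality across presets, trace variants, and housing
conditions. The full standard experiment is about 4.4 million agent
timesteps per 10-run cohort and takes a few seconds compiled; the 30-day
inter-session condition is about 60 million timesteps.

## Numerical choices

* Softmax probabilities are computed with the shift-by-maximum trick, so
  arbitrarily large $|M|/T$ cannot overflow.
* Critic weights are clipped at $\pm|R_{\text{shock}}|$ and actor weights
  floored at 0, as the update rules require.
* Magnitudes that decay below $10^{-250}$ are snapped to exact zero.
  Geometric decay over multi-week inter-session periods would otherwise
  drive weights and traces into the denormal floating-point range —
  behaviorally indistinguishable from zero but an order of magnitude
  slower to compute with.
* Selection needs no tie-breaking (it samples); the selected index is the
  first whose cumulative probability reaches the uniform draw, with the
  last allowed action as a guard against rounding at the tail.
* Each run uses one independent stream, seeded `base_seed + run index`;
  condition comparisons reuse the same seed block (a paired design that
  sharpens ordering tests).

## What the simulations do and do not show

The generator's defaults *are* the study conditions: trial and session
structure, the 18 000-step standard interval, cohort size 10, and the
preset parameter values. Simulated cohorts reproduce the qualitative
phenomena — fast WKY acquisition to ceiling, slow WKY extinction, SD
warm-up and its dependence on the inter-session interval — but none of
the biological detail: no freezing or other species-specific defensive
behavior competes with the lever, shock sensitivity is a single scalar,
and within-trial timing is coarse (10-s steps hide the 0.5-s shock
pulses, which is also why shock-count bookkeeping is out of scope).
Passing tests therefore establish nothing about real rats beyond what the
model's equations encode; they certify that the implementation realizes
those equations and their published parameterizations.

## Degenerate inputs and edge cases

Zero-length segments are skipped (e.g. `iti_len = 0` ends a trial at the
press), `trials_per_session = 0` yields a pre-period-only session,
`intersession_len = 0` chains sessions seamlessly (the continuous
condition also drops the pre-period), and `n_runs = 1` reports SEM 0
with a warning. Configuration files reject unknown keys outright rather
than guessing.
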