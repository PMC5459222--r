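---
title: "Reward-rate-optimal decision boundaries: model, solver and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-rate-optimal decision boundaries: model, solver and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative task
model, the average-reward dynamic program that yields optimal wait/go
policies, the exact reward-rate evaluator, the synthetic-cohort simulator,
and the boundary-inference chain — together with the numerical and design
choices a maintainer would want written down.

## The task model

A trial hides a binary world state, *up* or *down*. Cues
$\delta X \in \{+1, -1\}$ arrive one per interstimulus interval (ISI); each
points toward the true state with probability $u = \tfrac12 + \epsilon$,
where the drift $\epsilon \in [0, \tfrac12]$ sets the difficulty
($\epsilon = 0$: cues carry no information; $\epsilon = \tfrac12$: every cue
is truthful). After $t$ cues summing to $x$, the decision maker occupies the
lattice state $(t, x)$ with $|x| \le t$ and $t + x$ even. A correct choice
earns reward $R$ and a delay of $D_C$ ISI units before the next trial; an
error earns nothing and costs $D_I \ge D_C$. Blocks are fixed in duration,
so the ecologically sensible objective is the reward rate $\rho$ — expected
reward per ISI unit over the ongoing trial sequence.

`task_config()` holds the drift levels, their mixture weights (equal by
default, matching blocks in which easy and difficult trials are equally
likely), the two delays, the reward and the world prior. All times are ISI
units: experiments run at 200 ms and 50 ms presentation rates share a task
object, and the pipeline converts published millisecond parameters once, at
preset construction (e.g. $D_I$ = 10 s at a 200 ms ISI is 50 units).

## Beliefs on the lattice

With mixed difficulties, elapsed time is informative: a long uninformative
cue stream is evidence that the current trial is a hard one. `belief_at()`
computes, for a state $(t, x)$ with $n_\pm = (t \pm x)/2$ cue counts, the
joint posterior over (drift level $j$, world $s$) from the Bernoulli
likelihoods $u_j^{n_+}(1-u_j)^{n_-}$, and reports the world posterior, the
difficulty posterior and the predictive probability that the next cue is
$+1$. Internally all likelihoods are scaled by $2^t$ (each factor doubled),
which keeps products of up to a few hundred terms comfortably inside double
precision without log-space bookkeeping; posteriors are ratios and are
unaffected. The lattice-wide version (`belief_grid()`, internal) feeds the
solver.

## The average-reward dynamic program

Waiting costs exactly one ISI unit and moves to $(t+1, x\pm1)$ with the
*predictive* cue probability. Going earns $R$ with probability $P_c$ (the
larger world posterior), costs the realised delay, and restarts at $(0,0)$;
no extra time unit is charged for the response itself, because the
intertrial delay starts the moment the choice is made. With gain $\rho$ the
differential value $h$ satisfies

$$h(t,x) = \max\Big(\underbrace{-\rho + E[h(t+1, x\pm1)]}_{\text{wait}},\;
\underbrace{R P_c - \rho\,(P_c D_C + (1-P_c) D_I) + h(0,0)}_{\text{go}}\Big),$$

with $h(0,0) = 0$ and go forced at the truncation horizon `t_max`.

**Solver.** The wait transitions are acyclic in $t$ and every go returns to
the reference state, so for a *fixed* $\rho$ the optimality equations are
solved exactly by one backward sweep from `t_max` to 0. The map
$\rho \mapsto h_\rho(0,0)$ is strictly decreasing (every action consumes
time), so the optimal gain is its unique root, found by `uniroot()` to a
tolerance of $10^{-10}$. This replaces iterative schemes (policy iteration,
relative value iteration) with a deterministic two-level computation that
satisfies the same optimality equations at convergence; each sweep is
$O(t_{\max}^2)$ and the whole solve takes well under a second at the default
`t_max = 100`.

**Tie-breaking.** Where wait and go values are equal within `tie_tol`
($10^{-9}$), the action is go. This yields the lowest boundary consistent
with optimality and makes output deterministic.

**Horizon.** `t_max = 100` by default, with forced go at the horizon. For
mixed tasks containing a very hard difficulty the wait region genuinely ends
long before that (the boundary collapses to zero) and the action map is
exactly invariant to enlarging `t_max`. For single-difficulty tasks the
infinite-horizon wait region never ends, so truncation necessarily distorts
the last ~dozen time steps; the stationary region and the gain (truncation
bias of order the probability of ever reaching the horizon, $\sim 10^{-6}$
here) are unaffected, and the tests check invariance in exactly this sense.

**Boundary extraction.** `extract_boundary()` reports
$\theta(t) = \min\{x \ge 0 \text{ parity-valid} : \text{go}\}$, with two
lattice conventions. First, when the innermost valid state at $t$ is go
($x=0$ at even $t$; $|x|=1$ at odd $t$, where $x=0$ does not exist),
$\theta(t) = 0$: the policy guesses immediately and no lower boundary is
distinguishable on the lattice. Second, at times where the frontier lies
above the reachable cone, $\theta(t)$ is `NA` rather than an arbitrary
number. A constant underlying threshold therefore appears as heights
alternating between adjacent integers across odd/even $t$, and monotonicity
statements about boundaries are made per parity class.

## Exact reward rates and the landscape

`evaluate_reward_rate()` scores any boundary policy without simulation: per
drift level it propagates the occupancy distribution of the $\pm1$ walk
forward in time (only the *up* world — policies here are symmetric about
$x = 0$, so the down world is its mirror image), absorbing mass in go
states. That yields the accuracy $P_c$ and mean decision time $E[T]$ per
difficulty; numerator and denominator of the renewal-reward ratio are each
averaged over the mixture before dividing:

$$\rho = \frac{R\,\sum_j w_j P_{c,j}}
{\sum_j w_j \left(E[T]_j + P_{c,j} D_C + (1-P_{c,j}) D_I\right)}.$$

`reward_landscape()` evaluates this over linear boundaries
$\theta(t) = \max(0, a + \tan(m)\,t)$. Slopes are expressed in degrees,
$m = \arctan(\text{gradient})$ with the gradient in evidence units per ISI
unit — the same convention used when inferred slopes are compared. The
default grid is slopes $-80°\ldots80°$ in $2°$ steps and integer intercepts
$0\ldots15$: evidence lives on an integer lattice, so fractional intercepts
of a constant boundary are indistinguishable from the next integer up.
Boundary states count as go ($|x| \ge \theta$), matching the extractor. The
argmax is recorded with a deterministic tie-break: lowest intercept, then
the slope nearest zero.

Two structural facts worth knowing. The optimal policy's gain always
dominates the landscape (with equality for single-difficulty tasks, whose
optimum is itself a constant boundary — a useful cross-check between the
two code paths). And the landscape is asymmetric: above the flat optimum
reward falls off quickly with positive slopes, below it slowly with
negative ones, and matching $D_C$ to $D_I$ flattens the negative-slope side
further. This asymmetry is the package's tool for reasoning about *robust*
(rather than strictly optimal) boundary choices.

## The synthetic cohort

`simulate_trial()` implements two agent families on the cue stream:

* **rise-to-threshold** — respond the first time the internal evidence
  magnitude reaches $\theta(t)$ (sign of the evidence; fair coin at 0);
* **probabilistic boundary** — after each cue, go with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_T t + \beta_X |x|)$.

Perturbations, all independent and off by default: per-cue Gaussian internal
noise (SD `sigma_internal` per cue, so SD $\sigma\sqrt{t}$ after $t$ cues);
trial-to-trial drift variability (`sigma_drift`, with the perturbed
up-probability clamped to $[0.02, 0.98]$ so the Bernoulli draw stays valid —
the variability spec gives an SD but no truncation rule, so the clamp is
this package's choice); attentional loss (`p_attend`, each cue registers
independently); and an integer nondecision lag (`nd_samples` cues between
the internal decision and the recorded response, during which presented
cues keep arriving and are recorded). Simulated "optimal participants" in
the pipeline default to `sigma_internal = 0.5` and `nd_samples = 1`:
noiseless integration makes wait/go data perfectly separable, which is a
degenerate (if still handled) regime for the logistic fit, and 0.5 evidence
units per cue is a moderate level that leaves slope recovery intact; one
cue of lag matches what the response-locked estimator typically finds at a
slow presentation rate.

`simulate_block()` enforces the fixed-duration economy: trials accumulate
decision time plus realised delays, and a trial still in progress when the
block expires is discarded — only completed choices are recorded. A hard
per-trial cap of 500 cues guards against non-absorbing boundaries; capped
trials are flagged. `simulate_cohort()` draws and records one seed per
participant before simulating, so cohorts reproduce wholesale or
participant by participant.

What the generator deliberately does not emulate: visual interference
between cues, millisecond-level response-time structure within an ISI,
learning or drift of the boundary across a session, and sub-sample
nondecision lags. Passing recovery tests therefore show that the inference
chain is correct *given* the generative assumptions, not that those
assumptions exhaust real data.

## Inferring boundaries from records

**Nondecision lag.** Cues arriving after the internal decision match the
response only at the chance level set by the drift, while the cue that
triggered a threshold crossing always matches. `estimate_nondecision()`
reverses each trial, aligns on the response, computes the agreement
proportion $p_t$ at each index ($t$-th cue before the response; trials
shorter than $t$ are excluded from that index's denominator — the procedure
leaves this open and exclusion is this package's choice), and returns one
less than the first index with $p_t > 0.75$. The lag is estimated per
participant from the single-difficulty easy games and applied to all
conditions. `strip_nondecision()` removes the last `nd` cues and rewinds
the decision state; with `nd = 0` it is the identity, and trials left with
nothing before the lag are dropped and counted.

**The wait/go table.** Every cue seen is an observation: wait rows at
$t = 1 \ldots n-1$ with the running evidence and one go row at the final
state; an immediate guess is the lone row $(0, 0, \text{go})$. No
$(0,0,\text{wait})$ row is emitted — the first opportunity to act follows
the first cue. Evidence enters as the folded magnitude $X = |x|$: the task
and its boundaries are symmetric about zero, and a signed coding on
two-sided data would cancel the evidence effect entirely, leaving the
go-frontier unidentifiable. Mixed-game fits use the easy trials only by
default (like-for-like comparison against easy games); the difficult subset
is available for tasks whose hard difficulty is informative.

**Fit and line of indifference.** `fit_waitgo_logistic()` maximises the
Bernoulli likelihood of go given $(T, X)$ — or $X$ alone for the
fixed-boundary model. Noiseless threshold agents produce perfectly
separable tables on which the MLE diverges; the fit then switches to a weak
ridge penalty ($\lambda = 10^{-4}$ on $\beta_T, \beta_X$, never the
intercept, minimised by BFGS on the penalised deviance) and is flagged.
The line of indifference $X = -(\beta_T/\beta_X) T - \beta_0/\beta_X$ has
its slope reported in degrees; when $|\beta_X|$ is below tolerance the fit
is time-dominated and the slope saturates just inside $\pm90°$ — the
phenomenology of games whose decisions are driven by elapsed time. Because
steeply rising and steeply falling boundaries are near-identical behaviour,
slopes are compared circularly:
$\Delta m = ((m_e - m_m + 90) \bmod 180) - 90 \in [-90, 90)$. One caveat
the tests respect: when a point estimate saturates near $-90°$, a raw
difference slightly above $90°$ is folded by this map onto the opposite
sign, so *monotone tracking* of true differences is asserted on raw
differences while the range bound is a property of the circular map itself.

**Uncertainty and exclusion.** `bootstrap_slope_ci()` resamples whole
trials (not rows — rows within a trial are dependent), 1000 replicates by
default, and returns 95% percentile bounds; non-converged replicates are
dropped and more than half lost is an error. `binomial_exclusion_test()`
excludes a participant whose correct count cannot be distinguished from
chance by a two-sided exact binomial test at $\alpha = 0.05$ (the level is
this package's choice).

## Model selection

`compare_boundary_models()` fits both boundary models and compares
$\mathrm{BIC} = k \ln n - 2\log L$. The observation count $n$ is the number
of wait/go rows — each opportunity is a Bernoulli observation under the
model — with per-trial counting available as a sensitivity analysis. Equal
model priors give the posterior probability of the time-varying model as a
logistic transform of the BIC gap, computed from the difference for
stability. $|\Delta \mathrm{BIC}| < 2$ is reported as ambiguous; 2 is the
conventional "positive evidence" edge and the margin is configurable.

For recovery studies the generating agents are noiseless
integrate-to-boundary agents: with internal noise, the evidence the
experimenter records mismeasures the internal state, and a genuinely flat
internal boundary produces an apparent collapse in the recorded data. Slope
*difference* analyses are robust to this (and to drift variability and
attentional loss — the recovery tests verify both at
$\sigma_{\text{drift}} = 0.35$ and $p_{\text{attend}} = 0.7$), but absolute
model selection is not, so the model-recovery claim is made under the clean
generative rule.

## Pipelines and problem sizes

`run_experiment_preset()` chains everything for six parameter sets spanning
slow (200 ms) and fast (50 ms) ISIs, short ($D_I/3$) and matched correct
delays, and two difficulty mixtures (0.22/0, where the optimal mixed
boundary collapses; 0.40/0.10, where it rises slightly). The paired cohort
comparison uses easy vs mixed-easy slopes, except in the moderate-mixture
preset where the informative comparison is difficult vs mixed-difficult.
The cohort t-test is an off-the-shelf paired `t.test()` on circular slope
differences, reported for parity with standard practice.

Problem sizes in the shipped tests are desk scale, chosen as the smallest
that make the checks sharp: lattice horizons of 40–100 steps, landscape
grids of ~1300 cells, cohorts of 5–10 agents at 150–400 trials each for
recovery and direction checks, $10^5$-trial Monte-Carlo validation of the
exact evaluator (3 standard errors), and 40 replicates per condition for
model-recovery rates. The full-size study conditions (24 participants,
published block durations) are the pipeline defaults.

## Known limitations

* Boundaries are symmetric and the evaluator exploits that; asymmetric
  payoff structures would need a two-sided propagation.
* Only linear boundary families are scored on landscapes; the optimal
  policy itself is unrestricted.
* The logistic boundary model conditions on the recorded evidence path;
  it cannot separate internal noise from boundary stochasticity, which is
  why absolute slopes are biased (steeper than truth for collapsing
  agents) even though comparisons across conditions remain valid.
* Continuous-time diffusion limits, urgency-gating and stochastic-deadline
  mechanisms are out of scope.
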