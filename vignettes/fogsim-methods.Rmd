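---
title: "The fogsim model: risk-sensitive actor-critic loops and freezing of gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fogsim model: risk-sensitive actor-critic loops and freezing of gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogsim)
```

## The scientific problem

Freezing of gait (FOG) is a paroxysmal inability to step that affects a
subgroup of Parkinson's Disease patients ("freezers"). Virtual-reality
experiments in which seated patients "walk" with foot pedals through a
corridor of doorways while responding to Stroop word cues show that
freezing events are provoked by *decision conflict* (a colour word whose
ink disagrees with its meaning) and by *cognitive load* (blocks of complex
cues), and that dopaminergic medication partly relieves them. `fogsim`
implements a cortico-basal-ganglia account of these findings: two
actor-critic loops — a cognitive loop that reads the word cue and a motor
loop that views the upcoming doorway — each learn a risk-sensitive Utility,
and their combined evidence drives a drift-to-threshold footstep generator.

## The model

### Risk-sensitive Utility

Both loops value states by the usual temporal-difference (TD) machinery:
the Value `Q` estimates expected (discounted) reward and is updated by the
TD error `delta`, the model's dopamine correlate. A second function, the
Risk `h`, tracks the variance of the TD error through the risk prediction
error `xi = delta^2 - h`. Decisions are made not on Value but on Utility,

```
U = Q - alpha * sign(Q) * h ,
```

where `alpha >= 0` is the risk sensitivity, the proposed correlate of
striatal serotonin. The sign term makes risk a penalty for positively
valued states and a bonus for negatively valued ones. We define
`sign(0) = 0` so an untrained state (`Q = 0`, `h = 0`) has a continuous
Utility and no spurious risk penalty.

Parkinsonian dopamine depletion is modelled by clamping every TD error at
a ceiling `delta*` (OFF state); medication adds a term `delta_med` to the
(possibly clamped) error, unconditionally — also when the error is
negative, which is the literal reading of the update rule we adopt. Only
an upper clamp is applied. The two loops carry separate ceilings, applied
during training and evaluation alike, with the motor ceiling the stronger
(putamen-dominant dopamine loss).

### The cognitive loop

The 13 task cues combine five words (STOP, WALK, RED, GREEN, BLUE) and
four ink colours (red, green, blue, neutral): 4 simple cues, 3 congruent
and 6 incongruent colour words. A cue is encoded as a 9-bit vector (word
one-hot + colour one-hot) and fed to a 9-5-2 sigmoidal network whose two
outputs are the action Values for walking and stopping. Training follows
the two-phase protocol: about 600 trials of simple cues only (priming
WALK/green toward walking and STOP/red toward stopping), then 1000 trials
of all cues with the simple+congruent pool presented twice as often as the
incongruent pool. On each trial an output node is selected by a softmax
competition, reward 1/0 is delivered for the correct/incorrect action, and
the prediction error `delta = r - Q_sel` (clamped by the group's dopamine
condition) updates the selected node's output weights and, by
backpropagation, all hidden weights.

The cue's uncertainty is read off the walk probability
`p_w = Q_w / (Q_w + Q_s)` as `h = p_w (1 - p_w) / 0.25`, so the maximum
Risk (at `p_w = 0.5`) is exactly 1. The walk Utility
`U_w = Q_w - alpha_cog * sign(Q_w) * h` is the loop's evidence: it is what
a presented cue contributes to the footstep generator.

### The motor loop

The agent is a disc of radius 0.5 on a corridor with 300 doorways spaced
4 length units apart, each independently narrow (2 units) or wide
(3 units), all 1.6 units high. Its state is a retina-like *view vector*:
120 degrees of horizontal and 90 degrees of vertical field, each split
into 50 sectors, giving 100 entries in {-1, +1}. A horizontal sector is on
when its centre ray passes through the open gap of the nearest upcoming
doorway; a vertical sector is on when its centre elevation lies below the
angle subtended by the door top. More sectors light up as the doorway
nears, so the code carries implicit distance; the height half
disambiguates a close narrow doorway from a distant wide one, which
subtend the same horizontal angle.

Two linear-sigmoidal approximators over the view vector give the motor
Value and Risk; passing a doorway pays +1, colliding with a post pays -1
(the agent bounces back and tries again). The Risk weights are updated
with `eta * delta^2 * phi` — the printed form, which we keep as the
default; a `risk_residual` switch enables the variance-residual form
`eta * (delta^2 - h) * phi` for users who want a Risk that can also
decrease.

The actor is the Go/Explore/NoGo (GEN) policy, a stochastic hill-climber
on Utility. With `dU = U(t) - U(t-1)`:

```
dZ = A_G * sig(lambda_G * dU) * dZ_prev
   + A_E * chi * exp(-dU^2 / sigma_E^2)
   - A_N * sig(-lambda_N * dU) * dZ_prev
```

Rising Utility reproduces the previous velocity (Go), falling Utility
reverses it (NoGo), and a flat Utility landscape leaves the Gaussian
exploration term `chi ~ N(0, I)` at full strength, gated by the width
`sigma_E`. Note the negated argument in the NoGo sigmoid: with a common
sign the Go and NoGo terms cancel identically at equal gains and the
policy would have no gradient-following behaviour at all; the negated form
is the only one with the intended limits (pure Go as `dU -> +Inf`,
reversal as `dU -> -Inf`). The forward velocity component is passed
through a sigmoid before the position update, so the agent can stall but
never walk backwards; the lateral component is untouched and the walls
(flush with the widest doorposts) simply stop it.

### From evidence to footsteps

A decision variable `s` — the intent to step — accumulates
`kappa(t) * ||dZ(t)||` each time step and triggers a footstep when it
crosses 1, resetting without carry-over; the steps between crossings are
the *step latency*. The drive is `kappa = b` (baseline) except from the
onset of a word cue, presented 2 length units before each doorway, when it
becomes `kappa = b + U_w` for that cue until the gated footstep completes.
Negative increments are floored at zero: a cue with strongly negative walk
Utility freezes the accumulator. One cue gates one footstep decision; if
the gated footstep has still not completed when the next cue arrives (or
the run ends), it is recorded as *censored* — a capped latency that always
counts as a motor arrest. This keeps each presentation's outcome
attributed to its own cue; without it a single frozen accumulator would
smear one giant latency across many doorways.

The gait metrics follow the experimental definitions: the *modal latency*
is the mode of a subject's integer latency distribution (ties broken
toward the smaller value; censored values excluded); a *motor arrest* is a
latency strictly greater than twice the mode (censored footsteps always
count); *MFSL* is the largest of the first three post-cue latencies
divided by the mode; the *doorway latency* is the largest latency
completed within 0.1 length units of a doorway plane, scaled by the mode.

## Group parameters

The group regimes (`group_params()`) are fixed by the published table:

| regime | group | delta*_mot | sigma_E | alpha_mot | delta*_cog | alpha_cog |
|---|---|---|---|---|---|---|
| conflict task | control | — | 0.5 | 0.5 | — | 0.1 |
| conflict task | non-freezer | 0.02 | 0.5 | 0.3 | 0.15 | 0.5 |
| conflict task | freezer | 0.005 | 0.2 | 0.1 | 0.04 | 1 |
| load task OFF | non-freezer | 0.02 | 0.5 | 0.3 | 0.15 | 1 |
| load task OFF | freezer | 0.003 | 0.1 | 0.1 | 0.08 | 7 |
| load task ON | both | as OFF + delta_med = 0.001 | | | | freezer drops to 1 |

Freezers combine strong dopamine clamps, narrow exploration, *reduced*
motor risk sensitivity and *raised* cognitive risk sensitivity — the
model's central prediction of a differential serotonergic role in the two
loops.

## Calibrated defaults

The remaining hyperparameters are not fixed by the published material, and
we fixed them once by staged grid search (`calibrate()` implements the
generic machinery) against the behavioural criteria the model is required
to satisfy for healthy controls — at least 95% cue-training accuracy, a
stable modal latency that does not differ between groups, and reliable
doorway passage after training — mirroring the original fitting procedure,
which optimised control parameters first and refined the rest by grid
search. The defaults are:

* cognitive network: slope `lambda = 4`, gain `A_Q = 1`, learning rate
  `eta = 0.2`, softmax temperature `tau = 0.2`, weights initialised on
  (-0.3, 0.3). The temperature matters: with too little exploration the
  unchosen action's Value never decays, every cue retains high Risk, and
  the load contrast between simple and complex cues disappears.
* motor critic: slope `lambda = 0.1` (the view-vector input sums over 100
  entries of +-1, so a shallow slope keeps the sigmoid responsive), gains
  `A_Q = A_h = 1`, `eta = 0.05`, discount `gamma = 0.9`, weights on
  (-0.01, 0.01).
* GEN actor: `A_G = A_N = 1`, `A_E = 0.3`, `lambda_G = lambda_N = 5`,
  velocity-clamp slope `lambda_vel = 5`. The exploration gain is the one
  navigation parameter with a strong effect on the latency base rate: at
  `A_E` near 1 the Parkinsonian groups' flat Utility landscapes make
  exploration dominate, their agents move *faster* than controls, and the
  modal latency loses its group invariance.
* accumulator baseline `b = 1.3`, threshold 1, per-segment step cap 500.

Each simulated subject is an independent draw: fresh weights, a fresh
corridor, and a per-subject RNG seed derived arithmetically from the
master seed, so arrest counts are invariant to subject ordering and a
single integer reproduces a whole experiment.

## Protocol sizes

`run_matar_protocol()` trains each subject's cognitive network
(1600 trials), pre-trains the motor critic on 300 cue-free doorways, and
measures 52 cued doorways (each of the 13 cues four times, shuffled).
`run_shine_protocol()` measures 40 doorways in four blocks of ten
alternating low-load (simple) and high-load (complex) cues, with the
cue-action mapping counterbalanced across subjects and each subject run
OFF and ON medication from identical initial conditions. Statistics use
50 subjects per group. `sensitivity_sweep()` averages 20 subjects per
grid cell. On one CPU a full 50-subject protocol takes a few seconds with
the compiled engine.

## What the generator emulates — and what it does not

The synthetic subjects reproduce the *task structure* of the experiments:
the cue inventory and frequencies, the doorway geometry, the trial counts,
and between-subject variability arising from random initial weights and
stochastic training. They do not emulate pedal biomechanics, continuous
kinematics, inter-patient heterogeneity in disease severity, or any
neural detail below the two-loop abstraction (no explicit cortex, GPi or
brainstem rhythm generator). Passing the pattern suite therefore shows
that the *mechanism* — clamped TD errors plus asymmetric risk
sensitivities feeding a shared accumulator — suffices to generate the
group-level phenomena; it does not validate the model against individual
patient recordings.

## Numerical choices and degenerate inputs

Latencies are integer time-step counts, so group contrasts must survive
integer granularity; the calibrated baseline `b = 1.3` puts the modal
latency at 2–3 steps, where the published contrasts resolve. The walk
probability of a doubly-zero-valued cue falls back to 0.5 (maximal
uncertainty). Zero-velocity headings reuse the last nonzero heading
(initially straight down-track). Collisions bounce the agent back to its
pre-step position and the trial segment continues; a segment exceeding
500 steps is closed as capped and counts as an arrest. The statistics
layer returns `p = 1` for degenerate (zero-variance) tables — an
identical modal latency in every subject is evidence of no group
difference, not an error.

## Known limitations

* The medication term alone does not reduce freezer arrests at
  `alpha_cog = 7`: complex-cue walk Utilities sit several units below the
  freezing threshold and `delta_med` of order 0.001 cannot lift them; the
  simulated ON-state improvement comes from the accompanying drop of
  `alpha_cog` to 1. This matches the published observation that the
  medication factor by itself "did not produce the same effects" and the
  cognitive risk sensitivity had to be reduced — but it also means the
  model cannot reproduce an arrest decline driven by `delta_med` alone,
  and the corresponding sweep comparison is reported as failing in the
  acceptance suite.
* Among congruent cues, the conflict-loaded RED(red) carries reliably
  more Risk than GREEN(green), but BLUE(blue) — whose word and colour are
  unseen during priming — retains comparable Risk under the freezer
  clamp, so the three-way maximality of RED(red) is not robust.
* The non-freezer vs control MFSL difference is at noise level: the
  non-freezer complex-cue walk Utility stays positive, so its gated
  footstep is no slower than baseline; the group effect in the conflict
  task is carried almost entirely by freezers, as in the published
  figures.
* Motor-loop group signatures are weaker than cognitive ones. Untrained
  agents already pass about 90% of doorways (the walls funnel them), so
  passage success shows no visible learning curve, and the collision-rich
  near-door dynamics leave the Value surface nearly flat — what the motor
  critic learns robustly is the *Risk gradient*: trained Risk saturates
  near the doorway and vanishes far from it, reproducing the
  speed-accuracy tradeoff as NoGo-driven slowing on the approach. The
  mean motor Utility on the approach consequently does not order controls
  above non-freezers above freezers under these defaults (the control
  group's higher motor risk sensitivity multiplies its Risk); the
  group-level gait contrasts are carried by the cognitive channel and the
  near-door latencies.

## A worked example

```{r example, eval = FALSE}
library(fogsim)

res <- run_matar_protocol(n_subjects = 50, seed = 1)
m <- res$metrics

# modal latency is group-invariant
aggregate(value ~ group, m[m$metric == "modal_latency", ], mean)

# conflict cues slow freezers
mf <- m[m$metric == "mfsl_cue" & m$condition == "RED(red)", ]
aggregate(value ~ group, mf, mean)
run_statistics(m[m$metric == "mfsl_cue", ], within = "condition")
```
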