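---
title: "Modelling context-free savings in force-field adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling context-free savings in force-field adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When people adapt reaching movements to a velocity-dependent curl force
field, wash the adaptation out, and then meet the same field again, they
re-learn faster and start better — *savings*.  This package asks whether
savings can arise without any contextual cue signalling the field's
presence, purely from the geometry of a high-dimensional recurrent
controller, and it probes the candidate neural substrate: a *uniform
shift* of preparatory activity that persists after behavioural washout.

The model is a gated recurrent unit (GRU) policy that receives a
17-dimensional input — target position, a go cue and endpoint position
delivered through a 70 ms visual delay, and muscle lengths and velocities
through a 20 ms proprioceptive delay — and emits six muscle stimulation
commands through a sigmoid output layer.  The commands drive a planar
two-joint arm actuated by six Hill-type muscles (shoulder, elbow and
bi-articular flexor/extensor pairs).  A curl field applies the endpoint
force

F = b [[0, -1], [1, 0]] v,

always orthogonal to the endpoint velocity `v`, with gain `b` in N s/m
(`b = 0` null field; `|b| = 8` the trained field).

## The plant

The full-scale study conditions defer the musculoskeletal model to an
external simulator whose internal equations are out of scope here; a
simplified rigid-tendon Hill-type plant with the same interface is
implemented and documented as an approximation: a
first-order activation filter (time constant 50 ms), Gaussian
force-length and sigmoidal force-velocity scaling, constant signed moment
arms (muscle length affine in joint angles, optimal at the reference
posture), two-link rigid-body dynamics with closed-form mass and
Coriolis terms, light viscous joint damping, smooth soft joint limits,
and semi-implicit Euler integration at 10 ms.  The qualitative phenomena
of adaptation — not an exact reproduction of any particular plant — are
the target, so geometry (0.30/0.33 m links, 1.8/1.2 kg) and muscle
parameters are round human-like values, all configurable through
`arm_config()`.

Because the curl field enters through the endpoint Jacobian transpose,
its joint torque reduces analytically to
`tau = b L1 L2 sin(q2) (-qd2, qd1)`, which both the forward pass and the
hand-derived reverse pass exploit.

## Training objective and its conventions

The rollout loss is, per time step and averaged over steps and episodes,

L_t = 1e3 |x* - x|_1 + 1e5 j'j + 1e-1 (f'f + 3e-3 fd'fd)
      + 1e-5 (h'h + 1e2 hd'hd)

where `x*` is the goal (the start position before the go cue and on catch
trials, the target after it), `j` the jerk (third difference) of endpoint
position, `f` the muscle forces and `h` the hidden activity.  Two
conventions matter and are deliberate:

* **Derivatives are per simulation step**, not divided by dt.  In SI
  units the jerk term for a normal 10 cm reach is ~1e7 and dwarfs the
  position term (~50); the unique optimum of that objective is to not
  move, and a network trained under it never approaches its targets (we
  verified this directly).  With per-step differences the four printed
  coefficients balance, and smooth reaching emerges.
* **Muscle forces enter normalised by maximum isometric force**, so the
  muscle term is a fraction-of-effort penalty independent of the plant's
  absolute strength scale.

The jerk is the third derivative of position (not of acceleration);
stencils are forward differences with edge replication, so all regulariser
terms are exactly zero for a stationary trajectory.

The entire rollout — GRU, delays, plant, field — is differentiable, and
the reverse pass is hand-derived in compiled code.  It is verified
against central finite differences: smooth loss terms agree to ~1e-5
relative; the position term's L1 kink makes finite differences themselves
unreliable near error sign changes, so its check uses kink-free episodes.

## Optimisation regimes

*Growing up*: Adam (lr 0.003) on batches of 32 random point-to-point
reaches drawn uniformly from the joint box, 50% catch trials (no go cue;
the goal stays at the start, which suppresses anticipatory commands), go
times uniform on 100–300 ms, 1 s episodes (100 steps).

*Experimental phases*: plain batch-local gradient descent on centre-out
batches (4 repetitions x 8 targets on a 0.1 m circle around the endpoint
of the shoulder-60°/elbow-90° posture), in the order NF1, FF1, NF2, FF2,
with only the recurrent cell plastic: input and output maps, their output
bias, and the learnable initial state are frozen after growing up.  Gate
biases belong to the recurrent cell and stay plastic — that is our
reading of "only the hidden recurrent weights change", and it is recorded
here as a design choice.  No observation ever encodes the field gain.

A learning rate is only meaningful relative to an implementation's
gradient scale.  Under this implementation plain gradient descent on the
composite loss is stable only for steps below ~2e-4 (we measured the
same-batch descent directly; larger steps oscillate in the stiff
smoothness directions and *degrade* straightness).  The full-scale
configuration keeps 0.005 (the full-scale study value) as its default; the
documented reduced presets use 1e-4, which reproduces the gradual,
few-hundred-batch adaptation curves that the learning-rate analyses
need.

## Behavioural measures

Lateral deviation is the maximum-magnitude signed perpendicular distance
of the post-go-cue path from the start-target chord, positive clockwise
(negative z of the cross product in the y-up frame).  One subtlety is
axis convention: the printed curl matrix rotates velocity by +90° (CCW)
in a y-up frame although the `b > 0` field is described as "clockwise";
rather than guess the original axes we implement the matrix verbatim and
run all savings analyses on the *field-aligned* deviation
`-sign(b) x deviation`, positive when the hand deviates the way the field
pushes — a presentation that is invariant to axis handedness.

Learning curves (per-batch mean signed deviation over the non-catch
reaches, measured before each batch's update so entry 0 is true batch-0
behaviour) are smoothed with a 5-batch moving average and fitted with
`y = alpha exp(-r x / 1000)` by nonlinear least squares; `r` may be
negative (worsening), which the opposite-field control requires.  Savings
is classified strictly: rate savings `r_FF2 > r_FF1`, deviation savings
`dev_FF2(0) < dev_FF1(0)`, ties count as no savings.

## Neural geometry

Preparatory activity is sampled exactly 340 ms before the go cue and the
endpoint force 90 ms after it (early acceleration).  Training episodes
(go at 100–300 ms into a 1 s trial) cannot host a go - 340 ms sample, a
tension present in the source protocol itself; analyses therefore use
dedicated evaluation episodes (1.5 s, go fixed at 0.5 s) in which the
preparatory state has settled.  This is our documented resolution of an
ambiguity, not something the protocol prescribes.

TDR solves `H = [F 1] W` by least squares on the baseline phase, takes
the first two columns of the pseudo-inverse of `W` (SVD cutoff 1e-12) and
orthonormalises them by Gram–Schmidt in column order.  The uniform shift
is the target-averaged preparatory difference FF1 - NF1, orthogonalised
against that plane; projections of all four phases (grand mean removed,
recomputed per analysis) are affinely rescaled so NF1 maps to 0 and FF1
to 1.  The endpoint force used for `F` is the muscle-generated force
(Jacobian-transpose-inverse of the muscle torques), excluding the
external field — TDR is fitted in the null field where the distinction
is moot anyway.

The causal probe adds `m x us` to the stored hidden state at the single
state index go - 340 ms, before the output layer and the next recurrent
step read it, and measures the dose–response of FF2 batch-0 deviation for
`m` in {-2, -1, 0, 1, 2}.

## Synthetic fixtures

Every analysis stage has a planted-truth generator so it can be tested
without any training run: preparatory matrices built as
`H = [F 1][M; c]` plus a planted shift orthogonal to the readout, a
washout fraction `w` of the shift remaining in NF2, and i.i.d. Gaussian
noise expressed relative to the signal RMS; arcs with known signed
offsets for the deviation metric; exponential curves with known
`(alpha, r)`.  With zero noise the full pipeline returns normalised
projections (0, 1, w, 1) exactly.  What the fixtures deliberately do not
emulate is trained-network temporal dynamics — those are exercised by the
real scaled-down protocol — so passing fixture tests certifies the
analysis algebra, not the biology.

## Problem sizes

The full-scale study conditions are 40 networks of 128 units trained for
~46,400 batches each; that is cluster-scale.  The package ships three
presets:

* `experiment_config()` — the full-scale conditions (defaults).
* `tiny_config()` — a desk-scale preset (64 units, 2,000 growing-up
  batches of 16, phases 800/800/2000/800, 5 seeds).
* `micro_config()` — the suite scale: 3 seeds, 64 units, 6,000 growing-up
  batches of 32, phases 1400/450/1400/450 (null-field
  phases of equal length, each ~3x the force-field phases, as at full
  scale), phase lr 1e-4.  This is the
  smallest configuration at which adaptation, the after-effect, washout,
  deviation savings and the persistent uniform shift are all expressed;
  a full multi-seed run (main plus opposite-field control) completes in
  roughly a quarter of an hour on one CPU.

## Known limitations

* Micro-scale preparatory dynamics contract quickly (time constant a few
  steps), so a one-step perturbation injected 340 ms before the go cue
  decays ~99% before movement; the dose–response over the shift direction
  has the correct sign but micron magnitude, whereas fully trained
  networks hold perturbations to a new steady state.  Expect the
  perturbation ordering to be the weakest end-to-end property at reduced
  scale.
* Learning-rate savings (`r_FF2 > r_FF1`) is noisier than deviation
  savings at reduced scale, consistent with the observation that the
  probability of savings falls as network capacity and training depth
  shrink.
* The plant is a documented simplification: no tendon compliance, no
  gravity, constant moment arms, smooth soft limits.
* Exponential fits on nearly-flat curves are weakly identified; failed
  fits are returned flagged rather than silently dropped.
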