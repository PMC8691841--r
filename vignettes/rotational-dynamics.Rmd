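---
title: "Feedback-driven controllers of a two-link arm and the analysis of rotational population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-driven controllers of a two-link arm and the analysis of rotational population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`rotdyn` simulates a closed sensorimotor loop: a two-layer neural network
controls a planar two-joint arm through six lumped muscles and receives
sensory feedback about the arm after a physiological delay. The package
then asks a population-dynamics question of the resulting activity: how
much of it is captured by a rotational (skew-symmetric) linear dynamical
system, the signature commonly attributed to intrinsic pattern-generating
circuitry in motor cortex? Because the controller's activity is shaped by
delayed sensory feedback, the package lets one examine whether rotational
structure requires intrinsic recurrence at all (the NO-REC variant answers
that question directly).

## Plant

The arm is the standard planar two-link model used throughout the
optimal-control literature: configuration-dependent inertia matrix,
Coriolis/centripetal terms, and joint viscosity, restricted to the
horizontal plane so gravity plays no role. The state vector is
`[theta_elb, theta_sho, omega_elb, omega_sho]` (radians), torque vectors
are `(shoulder, elbow)` in N m, and integration is forward Euler at
`dt = 10` ms. The rigid-body parameters (`arm_params()`: link lengths
0.30/0.33 m, masses 1.4/1.0 kg, inertias 0.025/0.045 kg m^2, centers of
mass 0.11/0.16 m, viscosity 0.05 N m s/rad) are the widely used planar-arm
set; they are exposed as arguments so any published variant can be
substituted.

Six muscles actuate the joints: monoarticular flexor/extensor pairs at
each joint and one biarticular pair. Moment arms are constant, 2 cm for
the monoarticulars and 1.5/2.0 cm (shoulder/elbow) for the biarticulars.
Muscle force is `activation * F_max * FL(l) * FV(v)` with normalized
length and velocity linear in the joint state through the moment-arm
matrix. The force-length curve is a Gaussian bump of width 0.3 centered
at the optimal length; force-velocity is a piecewise hyperbola with
`FV(0) = 1`, zero force at a shortening velocity of 10 optimal lengths/s,
and saturation at 1.3 for lengthening. These smooth surrogate forms stand
in for tabulated muscle models; the network adapts its weights to
whatever smooth gain modulation the curves impose, so results depend on
them only weakly. The reference posture at which all muscles sit at
optimal length is the workspace home posture (shoulder 45 deg, elbow 90
deg).

## Controller

Two leaky tanh layers (Equations as implemented in `step_network()`):

    h'  = (1 - l_n) h + l_n tanh(W_sh I + W_hh h + b_h)
    o'  = (1 - l_n) o + l_n tanh(W_ho h + W_oo o + b_o)
    m'  = (1 - l_m) m + l_m [W_ou o]_+

with `l_n = dt / 20 ms = 0.5`, `l_m = dt / 50 ms = 0.2`. The input vector
`I` concatenates the task-goal channels (none for posture; the target's
spatial position for reach and tracking; a GO cue for reach), the delayed
joint kinematics `x(t - delay)` and the delayed muscle activities
`m(t - delay)`; the delay is 50 ms (5 samples) by default, and the delay
line is primed with the trial's initial state so no artificial transient
occurs at trial start. The target position is coded as its displacement
from the home hand position scaled by 10 (`goal_scale`), which puts the
centimeter-scale workspace on roughly unit range, commensurate with the
radian-scale feedback channels. Coding the target in absolute meters
instead buries the across-target information under a large constant
offset and, empirically, leaves gradient-based training unable to escape
the never-move solution. In the NO-REC variant both recurrent matrices are
pinned to exact zero and the leak terms are dropped, making each layer a
memoryless function of its input — any temporal structure in a NO-REC
network is inherited from its inputs, which is the point of the variant.

Weights initialize uniformly on `[-1/N_inp, 1/N_inp]` (`N_inp` = number
of incoming connections of that matrix); biases start at zero. A
gaussian scheme with sd `g/sqrt(N_inp)` is available for studying
strong-recurrence initializations. The literal `g/N` scaling is also
available (`literal_gn = TRUE`); at 500 units it yields vanishing
recurrent variance, which is why the square-root convention is the
default.

## Tasks and objective

* **Posture**: hold the home posture; after 500 ms one of eight 0.2 N m
  joint-torque combinations (single-joint flexion/extension plus the four
  diagonal pairs) switches on for the remaining 1.5 s. A ninth, unloaded
  condition is included during training; analyses use the eight loaded
  conditions. The network receives no information about the load other
  than delayed sensory feedback.
* **Delayed reach**: 32 radial targets (16 directions at 2 and 5 cm).
  The target is visible from trial start; after 500 ms the GO cue
  (smoothed with a 20 ms SD Gaussian) drops and the hand must acquire the
  target within 500 ms and hold it.
* **Tracking**: 15 radial targets; after 300 ms of rest the target moves
  outward at constant velocity, reaching 5 cm at 1.2 s, its position fed
  to the network as a ramping input. There is no GO cue; movement is
  initiated by the moving target itself.

The loss is the summed squared kinematic error (joint angles and
velocities against the desired state) inside each task's penalty windows,
plus quadratic penalties on muscle (`alpha`), input-layer (`beta`) and
output-layer (`gamma`) activity at every step, normalized by `2 C T`.
Posture uses `alpha = 1e-4, beta = gamma = 1e-5` with the muscle penalty
raised to `1e-2` before load onset (so muscles are quiet by default);
reach and tracking use `alpha = 1e-3, beta = gamma = 1e-6`. The penalty
windows encode "arrive and hold": the initial hold period, then from 1 s
after load onset (posture) or 0.5 s after GO (reach) to trial end;
tracking penalizes position and velocity error at every step.

## Training

`train_network()` implements full-batch backpropagation through time in
vectorized R, including the analytic Jacobian of the arm dynamics
(inertia, Coriolis, viscosity, and the muscle force-length/velocity
gains) and of the delayed-feedback paths. Gradients are verified against
central finite differences in the test suite. Optimization is Adam
(learning rate 1e-2 at desk scale, global gradient-norm clip 1.0);
training stops when the loss is below `5e-4` and its running mean is flat
over a plateau window, mirroring the "small constant error" stopping
rule. One hazard is specific to the rectified muscle readout: a single
bad update can silence every muscle drive at once, after which the
rectifier passes exactly zero gradient and plain Adam can never recover
(the loss sits at the "never move" value forever). The trainer therefore
backtracks on collapse — when the loss exceeds 1.4x the best value seen,
it restores the best checkpoint, halves the learning rate and resets the
Adam moments (`train_config(backtrack_factor, max_restarts)`). The
posture task never triggers this guard; the self-initiated reach and
tracking tasks rely on it. Trainings at the package's desk scale (100-200 units per layer, the
regime all shipped analyses use) converge in several hundred epochs, a
few minutes each on one CPU; the 500-unit full scale behaves the same but
trains proportionally slower.

# The analyses

## jPCA-style rotational fits

`jpca()` follows the standard recipe: soft-normalize each unit by its
range plus a constant (5e-4 for network activity, 5 spikes/s for spike
rates, 0 for muscle and kinematic signals — low-amplitude network units
are damped rather than amplified), subtract the cross-condition mean at
each time point (removing all condition-independent signal), reduce to
the top principal components (6 for network populations, 4 for the six
muscles, 2 for the four kinematic signals), differentiate by forward
first differences within each condition (the last sample of each
condition contributes no pair), and fit `Xdot = M X` by least squares
twice: unconstrained, and constrained to the skew-symmetric subspace via
closed-form normal equations over the d(d-1)/2 basis coefficients. The
constrained fit's conjugate eigenvector pairs span the jPC planes, ranked
by eigenvalue; frequencies are `|eigenvalue| / 2 pi` in Hz, and each
plane's variance accounted for is measured against the total variance of
the full preprocessed matrix. `R^2` uses the row-mean-removed derivative
as its reference for both fits so the two are directly comparable.

Analysis windows: posture activity is analyzed over a 300 ms window
beginning 20 ms after the sensory delay has elapsed (70-370 ms post-load
at the standard 50 ms delay; from load onset when the delay is zero) —
before feedback arrives the network cannot know a load occurred. Reach
activity is aligned per condition to movement onset (first sample at
which hand speed exceeds 5% of its per-condition peak) and analyzed over
the first 300 ms of movement; this window is not shifted by the delay
because the GO cue, not sensory feedback, initiates the state change.
Tracking is analyzed from a common movement onset (the median of the
per-condition detections, keeping the tensor rectangular) to trial end.

Two numerical caveats worth knowing. First, differencing amplifies noise
by `1/dt`, so jPCA `R^2` degrades quickly with additive noise even when
frequencies remain recoverable — the synthetic-data tests quantify this.
Second, a plane's rotation frequency is only resolvable if the analysis
window covers an appreciable fraction of its period; the frequency
recovery checks therefore use 0.8 s of planted data, where a 0.5 Hz
plane completes 40% of a cycle, rather than the 300 ms analysis window.

## TME surrogates

`tme_test()` asks whether an observed rotational fit exceeds what smooth,
condition-tuned, population-correlated — but otherwise unstructured —
activity would produce. The maximum-entropy distribution over tensors
with given mode-wise covariances (units, conditions, time) is Gaussian
with a Kronecker-structured eigenbasis; its eigenvalue tensor is
`1/(l_u + l_c + l_t)`, with the Lagrange multipliers found by numerically
matching each mode's marginal eigenvalue spectrum (BFGS with analytic
gradients; rank-deficient covariances are floored at 1e-10). Surrogates
are drawn from the preprocessed tensor's covariances — matching the
statistic's input — and each surrogate is re-centered and analyzed
identically to the data. P-values use add-one smoothing,
`p = (1 + #{surrogate >= observed}) / (n + 1)`, so 1000 surrogates give a
floor of p = 0.001. The test is refused a clean bill below 30 units
(a warning) because the surrogate distribution becomes unreliable for
small populations; for the six muscles and four kinematic signals the
package instead offers `downsample_compare()`, which re-runs the analysis
on random matched-size subsamples of the network population. Note that a
small subsample genuinely loses rotational structure — it sees the
latents through a non-orthogonal loading — which is precisely why the
matched-size control, not TME, is the right comparison there.

## Decoding, current ratios, robustness

`decode_jpc_from_feedback()` regresses the jPC-plane trajectories on the
time-aligned sensory feedback the network actually received (delayed
kinematics and muscles, plus GO/target channels where present); high
`R^2` means the plane dynamics are already present in the network's
inputs. A time-shuffle control is built in. `current_ratio()` compares
recurrent (`|W_hh h|`) and sensory (`|W_sh I|`) currents per unit.
`noise_robustness()` trains controllers under different feedback gatings
(continuous, a 200 ms post-perturbation pulse, or none) and measures
endpoint error under multiplicative signal-dependent motor noise
(`sd = sqrt(level) * |command|`, the 0.8 level being the "80% of the
motor command" condition); noise is applied at test time only. In the
pulse and none gatings, the withheld feedback channels are held at the
trial's initial condition — the pre-perturbation steady state — rather
than at a frozen copy of recent feedback, which keeps the gating
differentiable-free and is equivalent before the perturbation arrives.
`delay_sweep()` retrains at 0/50/100 ms delays, shifting the posture
analysis window by the delay.

# Synthetic ground truth

`planted_rotation_population()` builds tensors whose latents follow
`zdot = S z` with block-diagonal skew `S` (one block per plane frequency,
plus an optional symmetric expansion mode), each condition carrying a
random phase and amplitude on the same planes — the "same dynamics,
different initial conditions" structure that underlies condition-wise
rotational analyses. Latents are projected to units through a random
orthonormal loading with optional additive noise (parameterized directly
or via a target signal-to-noise variance ratio). Because the generator
returns its ground truth (S, loadings, latents), every analysis stage has
an oracle: noiseless single-plane data must be fit at the closed-form
discretization values (`sin(w dt)/dt` skew coefficient), planted
frequencies must be recovered within stated bands at stated SNRs, TME
must reject planted rotations and stay calibrated on its own null.
`smooth_spikes()` turns spike timestamps into rate tensors with symmetric
or causal (past-only) Gaussian kernels of 30 ms SD, each spike's discrete
kernel normalized to unit area on the grid.

What the generator does not emulate: spiking variability, non-Gaussian
tuning, firing-rate nonnegativity, or the condition structure of real
reaching data. Passing the planted-data tests therefore validates the
analysis pipeline's arithmetic and calibration, not any claim about
biological populations.

# Design choices and limitations

* The network equations use tanh activations (the rectifier is reserved
  for the muscle layer); layer activities are bounded in (-1, 1) and
  muscle activations are nonnegative by construction.
* The update order is strictly causal: each quantity at `t + 1` depends
  only on quantities at `t`. A consequence of the two-layer chain plus
  the muscle integrator is that the earliest muscle response to a
  perturbation occurs a few samples after the 50 ms sensory delay
  (about 90 ms post-load at `dt = 10` ms), which the behavioral tests
  account for: no response may precede the delay.
* Desk scale (100-200 units) is the shipped configuration; all reported
  quantities are computed at this scale. Constrained-fit `R^2` values of
  trained networks carry substantial seed-to-seed spread at this scale,
  more than the unconstrained ones. In our runs the posture network's
  unconstrained fit, muscle fits, input-layer fits and feedback-decoding
  accuracy land close to the full-scale reference values, while the
  output layer's skew-constrained fit runs systematically lower (about
  0.25-0.35 rather than ~0.55) — at reduced width each unit carries more
  of the control load, so output transients are sharper and less
  sinusoidal, which penalizes the skew fit specifically. The reach
  network trains to a loss of about 1e-3 rather than 1e-4 within the
  package's epoch budgets, and its rotational metrics are correspondingly
  further from the full-scale values; the tracking network tracks to
  within ~5 mm but shows somewhat more rotational structure than the
  full-scale reference. The comparisons in the acceptance material use
  wide, pre-stated bands, and several remain outside them at this scale.
* HDF5 checkpointing is not provided; weights and reports serialize to
  JSON/CSV, which are diff-able and dependency-free.
* The tracking trial is pinned at 1.2 s of target motion; an alternative
  longer horizon can be configured via `tracking_task(movement = ...)`.
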