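---
title: "Simulated evaluation of a combined EMG + kinematic prosthesis controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated evaluation of a combined EMG + kinematic prosthesis controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transhumeral amputee retains the shoulder and the muscles of the proximal
humerus but loses the elbow and forearm. A self-contained prosthesis
controller can therefore only use signals available above the amputation:
surface EMG from the residual upper-arm muscles and the inertial motion of
the humerus itself. `myoreach` implements such a controller and the virtual
target-reaching protocol used to evaluate it, with a synthetic subject in
place of human participants: two time-delayed feedforward networks predict
elbow flexion/extension and forearm pronation/supination from six EMG
channels plus the 3-axis angular velocity and linear acceleration of a
humerus-mounted inertial unit.

The simulation covers both phases of the evaluation protocol. In the
*IMU-control phase* the virtual forearm follows the measured (here:
ground-truth) angles while sensor data are collected over a preset series of
64 reaching targets; the networks are trained on these data. In the
*ANN-control phase* the virtual forearm is driven by the network
predictions, closing the loop through a simulated user who keeps steering
the humerus by visual feedback, and performance is scored with Fitts-law
movement metrics.

## Kinematic conventions

All public joint-angle interfaces are in degrees, positions in centimetres,
accelerations in m/s²; rotations are 3×3 orthonormal matrices internally.
The shoulder-centred frame has x lateral, y superior, z posterior, so the
reaching workspace (x ∈ [−10, 20], y ∈ [−10, 20], z ∈ [−50, −40] cm) sits
anteriorly at negative z.

Thoracohumeral orientation uses the ISB-recommended description — plane of
elevation, elevation, axial rotation — implemented as the Y–X′–Y″ Euler
decomposition of the thorax→humerus rotation, with elevation kept in
[0, 180]°. The ISB recommendation fixes the angle meanings but the letter
sequence is a convention; it is configurable in the decomposition helpers.
At gimbal-degenerate poses (elevation ≈ 0° or 180°) the plane of elevation
is unidentifiable; because a streaming controller cannot raise an error
mid-trial, the previous plane value is carried forward (0 if none) and the
axial angle absorbs the remaining rotation, so recomposition still
reproduces the pose.

The elbow/forearm convention is an explicit assumption (the calibration
literature the protocol builds on does not print formulas): the
humerus→forearm rotation is `Rx(flexion) · Ry(pronation)` — flexion about
the humerus mediolateral axis, pronation about the forearm longitudinal
axis. Pronation follows the task convention of 90° = neutral (handshake)
and 30° = palm up. Ground truth built with this composition round-trips
through the extractor exactly, which is what the simulator and the online
error metric rely on.

The gyroscope model is the body-frame finite-difference rotation vector per
sample interval (backward difference: causal, like a strapped-down sensor);
the accelerometer model is the second finite difference of the sensor
position minus gravity, rotated into the sensor frame, so a resting sensor
reads 9.81 m/s² upward and a free-falling one reads zero. Both converge to
the analytic values as the step size shrinks and are tested against
closed-form oracles at 50 Hz.

## The synthetic subject

The arm is a two-segment chain (defaults: upper arm 33 cm, shoulder-to-hand
27 cm). The far corner of the stated workspace is 57.4 cm from the
shoulder, so the simulated reach including the hand segment must exceed
that; 60 cm total corresponds to a tall adult and leaves a margin for the
inverse kinematics. The rest (lap-like) posture puts the hand at
(0, −25, −15) cm with 90° pronation.

Reaches are straight minimum-jerk hand paths (the 10–15–6 quintic, peak
speed 1.875·d/T) of 4 s by default — chosen to match a comfortable
self-paced reach, consistent with the ~4 s median times-to-target the
protocol reports — with pronation interpolated along the same profile.
Inverse kinematics resolves the redundancy deterministically: the plane of
elevation is fixed to the target azimuth, axial rotation to zero, and
elevation/elbow flexion follow in closed form from the in-plane geometry.
A training "session" is reach → 0.5 s hold → return, repeated over the
preset 4×4×2 grid of 32 positions, first all at 30° and then all at 90°
pronation (64 targets).

Surface EMG is amplitude-modulated noise: each channel is unit-RMS
band-limited (15–450 Hz, 1000 Hz sampling) Gaussian noise multiplied by a
non-negative envelope. The band-pass is a linear-phase FIR with a flat
passband; a low-order IIR band-pass at these edges behaves like a
resonator, which would leave the carrier autocorrelated over tens of
milliseconds and corrupt 150 ms amplitude estimates. Envelopes are
`mixing_matrix %*% latents + noise_floor`, with K = 4 latent "muscles"
driven by deterministic rectified-linear functions of elbow flexion
angle/velocity and pronation angle/velocity:

* a biceps-like latent co-activated by flexion *and* supination (the
  supinating action of the biceps is what makes the palm-up vs neutral
  orientations separable from upper-arm recordings),
* a triceps-like latent (extension velocity),
* a supination-specific latent, and
* a brachialis-like pure elbow flexor.

The 6×4 mixing matrix gives each of four electrodes a dominant latent and
two electrodes deliberate cross-talk mixtures. Stochasticity enters in
three seeded places: the carrier noise, a slow (~2 Hz) multiplicative
envelope jitter (s.d. 0.05) emulating trial-to-trial variability, and the
additive envelope noise floor (0.05). The same seed reproduces a session
bit-for-bit.

What this generator emulates is the *statistical structure the controller
assumes*: outputs predictable from inputs, amplitude-coded EMG, slow
envelope dynamics, gravity-dominated accelerometry. What it does not
emulate: motor-unit spike trains, electrode lift-off and motion artifacts,
muscle fatigue, soft-tissue wobble, inter-subject electrode placement
variability, trunk motion. Passing tests therefore demonstrate the
correctness and internal consistency of the processing/learning/evaluation
chain under the stated conditions, not clinical performance on real limbs —
the absolute error levels of the synthetic subject are a free parameter of
the generator, and only the protocol's stated tolerances (4°/8°) are
treated as reproduction targets.

## Signal conditioning

Every 50 ms a 12-value feature frame is computed from the most recent
150 ms of raw data. EMG channels are detrended (window mean removed),
rectified, filtered with an exponential moving average (EMA) and averaged;
gyro/accel channels are EMA-filtered and averaged without detrend or
rectification (they are signed physical quantities). The kinematic window
is 8 samples at 50 Hz (inclusive endpoints). Frames are delay-stacked with
taps {0, 1, 2, 3} — the current frame plus three input time delays, 48
network inputs — a tap-set reading that is configurable, since "three input
time delays" is ambiguous between {1,2,3} and {0,1,2,3}. Predictions are
post-smoothed by the same EMA-then-mean operator over the last 0.5 s (10
ticks), using whatever history exists during warm-up.

Two numerical choices deserve note:

* **EMA constant.** The protocol does not state α. The window EMA is
  initialized at its first sample and then *averaged*; the composite weight
  on the oldest sample is `Σᵢ (1−α)^(i−1)/N`, which for α ≪ 2/N approaches
  ~40% — the amplitude estimate collapses onto one raw sample and its
  variance explodes several-fold. The default is α = 0.2 per stream
  (configurable), which keeps the initialization transient below 4% of the
  composite weight; in the range ~0.05–1 the trailing mean makes results
  only mildly α-sensitive. The implementation follows the literal
  "EMA, then mean" reading; a single-EMA readout variant can be obtained
  with α = 1 in the mean stage degenerating appropriately.
* **Per-window EMA vs streaming EMA.** The conditioning operators are pure
  per-window functions (no hidden filter state), which makes them
  oracle-testable and keeps every frame a function of exactly the last
  150 ms. This also bounds the controller's input latency structurally:
  a prediction at time t uses raw data no newer than t and no older than
  t − (3·50 + 150) ms.

## The networks and their training

Each degree of freedom gets its own two-layer network: 48 inputs → 6
logistic-sigmoid hidden units → 1 linear output, with per-feature z-score
input normalization stored in the model (necessary for mixed-unit inputs;
the protocol is silent on it). Training minimizes mean squared error by
full-batch L-BFGS with analytic gradients, run in segments of 200
iterations with early stopping on a randomly held-out 20% split (the
protocol states no optimizer or validation methodology; this choice is
documented and seeded). If the training-set RMSE does not reach
the tolerance — 4° for flexion/extension, 8° for pronation/supination —
the network is re-trained from a fresh seeded initialization with two more
hidden units, up to 20; exhausting the ceiling returns an explicit failure
report rather than an error, mirroring the protocol's escalation rule.
Given data, configuration and seed, training is deterministic.

On the default synthetic session (≈10,900 frames from 64 targets) both
networks meet their tolerances at the initial six hidden units, matching
the protocol's report that six sufficed for all subjects.

## The closed-loop test phase

The ANN-control phase runs ten 30 s trials of randomized targets drawn
from a workspace shrunk by 2 cm per face (the training workspace is
deliberately slightly larger so the networks never extrapolate). The
engine runs on a 100 Hz base clock with the IMU sampled at 50 Hz, EMG at
1000 Hz and the controller updated every 50 ms, so all three rates sit on
a common grid.

The largest invention in the package is the simulated user, since human
visual-feedback adaptation has no stated model. The intended (ground-truth)
arm keeps moving as a real limb would: the intended hand approaches an aim
point with a first-order lag (τ = 2 s, speed-capped), which reproduces
roughly 4 s reaches. The displayed forearm, however, follows the smoothed
network predictions, and every control tick the user shifts the aim point
by 0.3 × (target − displayed hand), an integral-style correction standing
in for the human compensating a miscalibrated controller; the analogous
correction applies to pronation. Intended angles drive the EMG/IMU
synthesis and serve as the reference for the online RMSE, exactly as the
measured angles do in the instrumented protocol. With oracle predictions
(displayed = intended) the engine reduces to IMU-control behaviour: zero
online error and every presented target acquired.

Targets follow the stated acquisition mechanics: inside when within 5 cm
and 30° for 0.5 s continuously; leaving early is an overshoot event. After
an acquisition the subject returns to rest, and the next target onsets when
the hand re-enters a 5 cm ball around the rest position; return ticks are
excluded from movement time, i.e. the Fitts clock starts at target onset.

## Metrics

`ID = log₂(D/W + 1)` with W = 10 cm and D measured from the hand position
at target onset. Throughput is ID over movement time (onset → acquisition,
hold included — the protocol does not say; the choice is switchable).
Overshoot is premature-exit events over targets *presented* (the stated
denominator is the total number of targets), unclamped since it is a ratio
of counts. Path efficiency divides the onset→acquisition straight-line
displacement by the polyline arc length, which keeps it ≤ 1 by the triangle
inequality. Time-to-target and time-remaining-in-trial are reported per
acquisition and per trial (full trial length when nothing was acquired).
Aggregates report both mean and median. All metrics are verified against
independent brute-force oracles on hand-built logs.

## Problem sizes and reproducibility

The default study conditions are used throughout: 64 training targets
(≈9 min of synthetic data, ≈10,900 frames) and ten 30 s test trials. The
unit-test suite exercises smaller sessions (2–8 targets) where only
operator correctness is at stake, and the full protocol in the end-to-end
suite; a full simulate→train→evaluate run takes a few minutes on one CPU
and is bit-reproducible under a fixed seed, with one top-level seed fanned
out to the session generator, the network initializations and the target
draws. `scripts/acceptance.R` re-runs the full training pipeline from
scratch and writes the two training-set RMSEs as JSON.

## Known limitations

* The synthetic EMG-to-angle signal strength is a generator choice; online
  RMSE levels and hit counts are comparable to the human study only in
  kind, not in magnitude.
* The simulated user is a proportional-integral caricature of human motor
  adaptation; it neither learns across trials nor exhibits reaction-time
  delays.
* The elbow rotation sequence and the EMA constant are documented
  assumptions where the protocol is silent.
* No familiarisation phase is modelled (there is no learning process to
  warm up).
* Inferential statistics across subjects are out of scope: the simulator
  population is not the study population.
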