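---
title: "Models and methods behind exogait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exogait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

exogait is a virtual simulator of walking with and without a
lower-extremity powered exoskeleton, together with the measurement
pipeline such a study runs: marker-based inverse kinematics (IK),
inverse dynamics (ID) with force-plate loads, GRF and EMG conditioning,
gait-event detection and ensemble statistics. Because no raw capture
data ship with the package, a first-class synthetic-trial generator
produces fully labelled fixtures with known ground truth; every claim
the test suite makes is a recovery-of-truth property on those fixtures,
not a reproduction of any particular laboratory's numbers.

## The multibody models

**Human.** The whole-body model has 24 rigid segments and 37 generalized
coordinates: a 6-DoF universal joint (three translations, then three
rotations) describing the pelvis pose in the ground frame; per leg a
3-DoF ball hip, a 1-DoF coupled knee, and 1-DoF pin joints at the ankle,
subtalar and metatarsophalangeal joints (7 DoF per leg); a 3-DoF ball
joint from pelvis to torso; and per arm a 3-DoF ball shoulder, pin
elbow, pin radioulnar joint and a 2-DoF universal wrist (7 DoF per arm).
The patella rides on the femur and the neck and head are welded to the
torso, so these segments carry inertia but no coordinates. The coupled
knee exposes exactly one coordinate; its prescribed tibia-translation
table is all-zero by default (a pure hinge), because the published
generic-model spline values are not available — a non-zero table can be
supplied and is honoured by forward kinematics, IK Jacobians, and the
velocity/acceleration propagation (natural cubic splines provide the
first and second derivatives the dynamics needs).

**Exoskeleton.** Seven segments — pelvic band, and thigh/shank/foot-plate
pairs — with four coordinates: pin hips and pin knees. The ankles are
welded to the shanks, as in the device. Segment masses and inertias are
*placeholders* summing to a configurable 23 kg device mass; the
manufacturer does not publish them, so they are required config inputs
for real work. `build_exoskeleton_model()` refuses non-pin hips/knees
and non-weld ankles in its default faithful mode.

**Coupling and lumping.** Human-robot interaction is a single 6-DoF
universal anchor joint from the pelvis to the pelvic band
(37 + 4 + 6 = 47 coordinates); an all-welded anchor variant gives 41.
For inverse dynamics the device inertia is *lumped*: each exoskeleton
segment's mass is added to its mapped human segment, the COM moves to
the mass-weighted combined COM, and both inertia tensors are transferred
there by the parallel-axis theorem, with the relative segment poses
taken from the coupled model's neutral configuration. The lumped model
keeps the human topology (37 coordinates). Total mass is conserved to
machine precision and the tensors stay symmetric positive semidefinite;
both are property-tested.

**Conventions.** SI units internally (m, kg, s, rad), degrees only at
I/O boundaries. The global frame is Z-up, X along walking progression,
Y left; gravity is (0, 0, −9.81) m/s² and configurable. Ball joints use
an intrinsic flexion–adduction–axial rotation sequence with default
axes (0,−1,0), (1,0,0), (0,0,1); flexion and dorsiflexion are positive,
extension and plantarflexion negative (the reporting layer negates for
"peak extension/plantarflexion" summaries, which are conventionally
quoted as positive magnitudes). The generic geometry — 1.80 m stature,
75.16 kg total mass, standard gait-model mass fractions, and a
conventional whole-body marker template extended with iliac-crest,
sacrum, second thigh/shank and forefoot markers — is an editable,
clearly approximate config (`default_human_config()`), since the
generic model it approximates does not publish its tables in print.

**Scaling.** `scale_model()` multiplies each segment's geometry (COM,
marker offsets, child-joint locations) by target-length/generic-length
ratios (a stature ratio where no per-segment target exists), scales all
masses by one factor so the total matches the subject (89.4 kg, 1.76 m
for the study subject), and scales inertia by (mass ratio)(length
ratio)². Identity anthropometry is an exact no-op.

## Kinematics

Forward kinematics composes poses along the joint tree, recording for
every coordinate its instantaneous global axis and point of
application. Those axis records give an *analytic* marker Jacobian
(`u × (x − p)` for rotations, `u` for translations, plus the coupled
knee's translation direction), verified against finite differences.

IK minimizes the weighted sum of squared marker distances per frame by
damped Gauss–Newton with Levenberg-style lambda adaptation
(accept/reject with λ÷3 / λ×10), converging when the step infinity-norm
falls below 1e-8 or the objective improvement below 1e-12, with at most
100 iterations — tolerances chosen to make results deterministic.
Frames are solved sequentially with the previous frame as warm start;
the first frame starts from the neutral pose shifted by the
observed-vs-model marker-centroid offset. Occluded markers are dropped
from the frame's objective — never interpolated — and any coordinate
whose subtree carries no observed marker is flagged under-determined
and held at its initial value. The marker RMS (weighted RMS of 3-D
marker distances) is reported per frame and as mean ± SD, with a
pass/fail flag against the 2 cm mean-RMS tolerance that is standard
practice for marker-driven simulators. Exoskeleton and human markers
are solved jointly in one objective with unit weights.

Differentiation uses an optional zero-phase 4th-order Butterworth
low-pass on the coordinates (default 6 Hz at 100 Hz sampling — a
standard gait-analysis choice; the source data's filtering ahead of ID
is not otherwise prescribed) followed by central differences,
second-order one-sided at the ends.

Human-robot angle comparisons subtract a constant offset first, because
the two templates define segment axes differently; the offset is
estimated as the trial-mean difference (the static-pose alternative
would differ only by noise on these fixtures). Encoder streams are
linearly resampled onto the IK clock before the offset-removed RMS.

## Dynamics

Inverse dynamics propagates angular velocity/acceleration and linear
velocity/acceleration exactly through every elementary joint transform
(no numerical differentiation inside the pass), forms each body's
inertial wrench `m(a_com − g)` and `I_g α + ω × I_g ω`, and projects
body and external wrenches onto each coordinate's instantaneous axis —
the virtual-work form of a recursive Newton–Euler pass over the tree.
External ground loads enter as force at the centre of pressure plus a
free moment. The six base coordinates receive whatever wrench the rest
of the system cannot explain; these *residuals* are reported separately
(`check_residuals()` also recomputes the whole-body balance
independently), and deliberately absorb unmeasured interactions such as
crutch forces rather than distributing them.

The forward-dynamics oracle exists for verification only (small
models): it assembles the mass matrix column-wise by unit-acceleration
ID calls with gravity off, the bias vector by a zero-acceleration ID
call, and integrates with `deSolve` at 1e-10 tolerances. It conserves
energy to ~1e-10 J over 10 s of free pendulum swing and reproduces the
small-angle period to 0.1%.

Moment normalization divides by the participant-plus-device mass for
assisted trials and by the participant's mass for unassisted trials,
and round-trips exactly.

## Signal conditioning

All offline filters are Butterworth designs from the `signal` package.
Zero-phase (forward–backward) filtering is the default for everything
offline: the source protocols are silent on phase handling, and phase
lag would corrupt event timing. A zero-phase pass doubles the effective
order (−6 dB rather than −3 dB at the design cutoff); "fourth-order"
always refers to the design order per pass, and single-pass filtering
is a flag. Because `signal::filtfilt` does no padding, the zero-phase
path is implemented as reflection-padded forward–backward passes with
steady-state initial conditions, which makes constants exact and ends
well-behaved.

The GRF chain low-passes force (and free-moment) channels at 15 Hz,
4th order, from 2000 Hz, optionally resampling to the 100 Hz marker
clock. Forces normalize to body weight — combined weight for assisted
trials. The EMG chain is, in order: subtract the quiet-standing resting
mean (taken before filtering, as the protocol's sentence order
implies), 30 Hz 4th-order high-pass (assumed Butterworth; the source
names only the order) to remove motion artifact, full-wave
rectification, 6 Hz 4th-order low-pass for the linear envelope, then
division by the muscle's maximum voluntary contraction (MVC) — the peak
envelope over that muscle's five isometric trials. Self-normalization
is exact by construction: the trial that sets the MVC reaches envelope
1.0 through the same pipeline.

## Events, cycles and reports

Foot strike and toe-off are upward/downward crossings of a 20 N
threshold on the filtered vertical GRF with a 50 ms debounce (both
configurable; the threshold and debounce are standard lab practice, not
prescribed by the protocols this mirrors), refined by linear
interpolation between samples. Stance splits into braking and
propulsion at the *last* posterior-to-anterior zero crossing of the AP
shear — an operational choice recorded here because no published
definition exists; a sign-pure stance degrades to a labelled warning.
Sit-to-stand and stand-to-sit phases follow the device protocol
(positioning lean, 3 s hold, motor-driven completion): the hold plateau
is located by a local-range mask and its boundaries refined to where
the torso angle enters/leaves ±0.5° of the plateau value, with the
motor-activation timestamp taking precedence for the hold end when
logged.

Curves are time-normalized onto a 101-point 0–100% cycle grid (the
universal convention). Ensemble curves carry pointwise mean and sample
SD (n−1); peak tables are the mean ± SD of *per-trial* peaks, never the
peak of the mean curve. Reports are written as deterministic CSV
(8 significant digits), so identical seeds give byte-identical files.

## The synthetic-trial generator

Joint waveforms are idealized truncated Fourier series — exact
trigonometric polynomials fitted by FFT, so values, velocities and
accelerations are all analytic. Knee flexion uses a raised-cosine-
squared swing bump whose maximum equals the commanded peak *exactly*;
hip flexion is a cosine between commanded extremes; ankle motion is a
small dorsiflexion bump plus a propulsion-phase plantarflexion bump;
the pelvis translates at the commanded speed with small surge, sway and
bob oscillations. The left and right legs are half a cycle out of
phase. Defaults are the two study conditions: assisted walking at
0.47 m/s with a 50.1° commanded peak knee flexion, an 8° propulsion
plantarflexion range and a pitched-forward torso, versus unassisted
walking at 1.11 m/s with 68.6° peak knee flexion and a 28° propulsion
range — the assisted condition deliberately locks the exoskeleton hip
and knee pins to the human waveforms (with a constant 12° frame offset
at the hip emulating the differing segment-axis definitions) and
restricts push-off, mirroring the reduced propulsion-phase
plantarflexion seen in device-assisted gait. Surge amplitudes were
chosen so the braking/propulsion shear peaks sit near the reported
values for each condition (~0.07 BW assisted, ~0.17 BW unassisted).
Trials differ through a small commanded-amplitude jitter (SD 0.2°) and
the per-trial noise streams; six trials per condition is the default,
matching the study's successful-trial count.

Ground loads are constructed, not simulated: each frame's whole-body
Newton–Euler resultant wrench is computed from the exact accelerations
and distributed between the feet by a raised-cosine stance-weight
function (10% double support; no flight phase), with the centre of
pressure progressing heel-to-toe under the stance foot and the free
moment taking up the remaining moment balance exactly. The loads
therefore satisfy the whole-body equations of motion to machine
precision — which is what makes the base-residual acceptance check
exact. Markers are forward-kinematics positions plus i.i.d. Gaussian
noise (default SD 2 mm, a realistic optical-capture figure) and
optional random occlusions. EMG channels are band-limited noise
carriers amplitude-modulated by phase-locked burst envelopes for the
8-muscle × 2-leg montage, with condition-scaled plantarflexor and
tibialis activity, a constant resting offset, five MVC trials per
muscle with a known maximum, and a noise-free quiet-standing trial.
Encoders are the exoskeleton joint angles plus a constant 5° offset and
1° white noise, sized so the IK-vs-encoder worst-case RMS stays within
the 3.3° figure reported for real device logs.

**What the fixtures do not emulate.** The waveforms are idealized
shapes, not captured human curves; there is no foot-ground kinematic
constraint, so feet translate slowly during stance and the COP path is
schematic; soft tissue artifact, marker misplacement, crutch forces and
strap interaction forces are absent; and EMG spectra are not
physiological. Consequently the fixtures reproduce the *kinematic*
contrasts they command (knee-flexion peaks, restricted push-off) but
not published joint-moment magnitudes — the fixture's knee moments do
not show the assisted-smaller-than-unassisted pattern a real device
study reports, and no test claims they do. Passing tests demonstrate
that the toolchain recovers known ground truth at realistic noise
levels, not that it reproduces any specific laboratory result.

## Verification design and problem sizes

The acceptance checks run at desk scale, sized to finish in minutes:

- *IK recovery*: six assisted-condition trials (47-coordinate coupled
  model, one gait cycle at 100 Hz plus a 0.35 s lead-in) solved
  noiselessly (coordinate recovery < 1e-6 rad, marker RMS < 1e-8 m) and
  with 5 mm marker noise (marker RMS < 2 cm). Joint-angle accuracy at
  5 mm noise is assessed on the reported angles (hip/knee/ankle
  flexion-extension) of the *conditioned* kinematics — the 6 Hz
  low-passed trajectories every downstream result consumes — over the
  filter's steady-state window (0.35 s trimmed per end). Raw per-frame
  hip/ankle errors at 5 mm noise are marker-geometry-limited to well
  above 1° for any anatomically plausible template, and single-marker
  toe segments are worse still; the conditioned reported angles are the
  quantity with a meaningful 1° contract.
- *ID round trips*: twenty random 3–5 DoF pin chains under
  computed-torque drives — a band-limited (≤ 1.5 Hz) reference motion
  realized exactly through single-frame ID, then re-integrated by the
  forward oracle. Exact-acceleration recovery is at machine precision;
  the default 100 Hz differentiation pipeline recovers torques to
  ≪ 2% relative RMS with filter transients excluded. The drives stay in
  the gait band on purpose: the 6 Hz conditioning default is a
  gait-analysis choice and rightfully attenuates faster content, so
  free resonant drives would test the filter's stop band, not the
  pipeline.
- *Statics and consistency*: closed-form pendulum torque (m g l_c),
  standing foot forces summing to weight, base residuals < 1e-6 of
  model weight on generated loads, and the exact one-model-weight
  vertical residual shift when loads are removed on a static pose.
- *Signals*: single-pass Butterworth cutoff gain 1/√2 within 1%, MVC
  self-normalization to 1.00 ± 0.02, resting envelope < 1e-3.
- *Pipeline*: six trials per condition through the full chain (IK →
  conditioning → ID → events → report), checking the commanded
  assisted/unassisted knee-flexion contrast within 1°, the
  propulsion-phase ankle-range contrast, mean ± SD table shape, and
  byte-identical reports under repeated seeds.

## Known limitations

Segment geometry, mass fractions and marker offsets are approximations;
exoskeleton inertial properties are placeholders. The lumped-model ID
reports *net human-robot* moments: separating human from device
contributions would require interaction-force measurements and separate
chain solutions, which is out of scope by design. Crutch and strap
forces land in the base residuals. The coupled knee's non-zero
translation tables are supported throughout, but the default is a pure
hinge. IK uses simple box-free local optimization — global relabelling,
gap filling and joint-limit constraints are out of scope. C3D input is
not supported; TRC/MOT/STO/CSV cover the pipeline.
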