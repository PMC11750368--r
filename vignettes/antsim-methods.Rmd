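---
title: "Methods: an embodied, physics-free ant navigation simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an embodied, physics-free ant navigation simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antsim)
```

`antsim` simulates a desert-ant-like hexapod agent navigating synthetic
visual and olfactory worlds with five classic insect controllers: central-
complex (CX) path integration, visual beaconing, a Zernike-moment visual
compass, bilateral odour-trail following and odour-plume tracking. The
package deliberately contains no rigid-body physics engine: the body is a
pure kinematic chain, and ground contact is replaced by stance-foot
odometry. This vignette explains each model, the tunable parameters and the
design decisions taken where the design was genuinely open.

## Body model and kinematics

The ant body is a joint tree with 40 joints: five per leg (ThCx, ThCz, CTr,
FTi, TiTa — named segment pair plus rotation axis), three per antenna, two
in the neck and two in the abdomen. Six leg tips and two antenna tips form
the eight tactile end-effector points. Segment lengths are stored at
real-animal scale (metres) and multiplied by a dimensionless `scale`
(default 100); hind legs are longer than middle legs, which are longer than
front legs, the characteristic desert-ant proportion. Measured morphometry
is not bundled; the defaults are plausible round numbers declared once in
`ant_morphology()` and replaceable via a YAML config.

Each leg-base frame is right-handed with x pointing outward along the leg's
rest direction and z up; front/middle/hind bases point 60/90/120 degrees
from the body axis (mirrored on the right). A consequence worth stating
explicitly: a positive ThCz rotation protracts a right leg but retracts a
left leg, which is why the yaw-control table below carries opposite signs
for the two sides at zero steering.

ThCx and TiTa are held at fixed angles (default 0), so each leg is a yaw
joint plus a planar two-link chain (femur, then tibia+tarsus as one
effective segment). Inverse kinematics is therefore closed-form: the target
azimuth sets alpha, the law of cosines (elbow-up branch) sets beta and
gamma. The forward-inverse round trip reproduces random reachable targets
to better than 1e-6 model units; unreachable targets (outside the annulus
`[|femur - tibia - tarsus|, femur + tibia + tarsus]`) raise an error naming
the offending distance. Angles at the gait level are degrees; rigid
transforms use radians; `deg2rad()`/`rad2deg()` are the only conversion
points. `homogeneous_transform()` uses fixed roll-pitch-yaw (x, then y,
then z) Euler order.

## Gait generation

The forward-kinematic (FK) gait drives the active triple (alpha, beta,
gamma) directly with piecewise-linear profiles parameterised by hip swing
`Sl` (degrees), lift swing `Sh` (degrees), direction `d`, rotation
configuration `theta` and half-swing step count `Sn`. A cycle is swing1
(lift + protract, `Sn` ticks), swing2 (lower + reach frontmost, `Sn`
ticks), stance (hip sweeps back, lift joints hold). The profiles are
continuous at every boundary and close the cycle exactly — a property the
test suite checks for 100 random parameter sets.

Steering enters through the per-side ThCz range R. For `theta >= 0` the
left legs take `R = Sl d (2 theta - 1)` while the right legs keep the full
stride `Sl d`; at `theta = 0` both sides stride forward, at `theta = 1` the
body spins CCW in place. For `theta < 0` we apply the mirror image (left
legs keep `-Sl d`, right legs take `Sl d (2 theta + 1)`): with our
right-handed mirrored leg frames this is the reading under which negating
`theta` mirrors the gait left/right and the robot turns CW while still
walking forward — taking the non-mirrored alternative literally makes the
robot walk backward for intermediate negative steering, which contradicts
both the gait's mirror symmetry and the behaviour the controllers assume.
The steering sign convention throughout the package is: `theta > 0` turns
the body CCW (left).

The inverse-kinematic (IK) gait instead prescribes Cartesian tip poses
relative to each leg's rest tip — step length `L`, step height `H`, with a
stance yaw that accrues to `theta` — and converts them through the leg IK.
The swing z-profile descends monotonically to `-H` by default (the literal
profile; a `lift` flag provides the lift-then-lower variant). The tip-pose
frame's x axis points rearward, so the stance path is a straight backward
sweep in the body frame, matching the FK stance arc's chord.

Coordination patterns share one mechanism: every leg's swing lasts `2 Sn`
ticks and the stance stretches to fill the cycle. Tripod (two antiphase
groups of three, cycle `4 Sn`), ripple (three antiphase pairs, `6 Sn`) and
wave (one leg at a time, back to front, `12 Sn`). Because stride per cycle
is fixed while cycle length grows, the emergent body speed orders tripod >
ripple > wave without any further assumptions. `Sn` defaults to 10 for
gait-level work; the scenario runners use `Sn = 5` (20-tick tripod cycles),
which keeps closed-loop experiments cheap at an angular resolution of at
most `Sl/Sn` = a few degrees per tick.

## Stance odometry (the physics replacement)

Feet in stance are assumed anchored to the ground. Between consecutive
ticks the stance tips' body-frame positions change by the commanded gait;
the rigid planar motion that best explains those displacements
(least-squares two-dimensional rigid fit, solved in closed form via the
2x2 cross-covariance) is applied inversely to the body pose. One stance leg
recovers translation only; zero stance legs leave the pose unchanged with a
warning. Stance membership is schedule-driven, not force-driven. This
replaces contact dynamics entirely: there is no slip, no adhesion, no
torque, and body height/pitch/roll are fixed. Emergent speeds are therefore
meaningful only ordinally (gait rankings, stride-length monotonicity),
never as absolute velocities of any physical robot.

## Visual world and sensors

Scenes are lists of analytic primitives (spheres, vertical cylinders,
cones) that render as dark silhouettes (intensity 0) on a bright background
(255) by exact ray casting — no rasterisation library, no lighting or
texture. Two cameras exist:

* **Panoramic** (72 x 72, spherical): columns sample azimuth uniformly over
  the full circle, rows sample elevation from zenith to nadir. Increasing
  the agent's yaw by `delta` shifts the image columns by exactly
  `72 delta / 2 pi` — the equivariance the visual compass relies on, exact
  by construction for whole-column rotations.
* **Binocular** (74 x 19 per eye, planar pinhole, horizontal FOV 2 rad,
  vertical 0.5 rad): eyes sit at the head sides separated by the
  morphology's eye separation, zero toe-in. A landmark at angle `phi`
  to the image-right of the axis projects to column
  `37 + f tan(phi)`, `f = 37 / tan(1)`. Eye renders average a 2 x 2
  sub-pixel ray grid: a single-ray renderer produces pixel-perfectly
  symmetric silhouette masks whose exact-zero centring offsets act as a
  discontinuous reward no real camera produces; anti-aliased edges remove
  that artifact.

`binarize_image()` marks pixels deviating from the background by more than
a threshold (default 18, the midpoint of the useful 10-25 range for
0-255 images).

The odour trail is optical: a 0-255 raster band on the floor with an
invertible world-to-pixel transform. The antennal trail sensor returns
`1000 x` the bilinearly interpolated normalised intensity under the tip, so
an on-trail reading is ~1000 and the trail-following thresholds
(`To = 900` on-trail, `Td = 5` bilateral deadband) are meaningful on that
scale. Antennae sweep sinusoidally in `moving` mode (amplitude 30 degrees,
period 20 ticks, left/right antiphase — unconstrained by data, exposed in
config); the trail runner samples the sensors every second tick within a
gait cycle and takes each side's maximum, so sweeping genuinely widens the
sampled band rather than just wiggling the tip between identical readings.

## Odour plume and wind

The plume is a set of Gaussian puffs released at the source (fractional
release rates accumulate), advected by the local wind plus per-puff
centerline-dispersion noise, with squared radius growing linearly and
puffs culled at the domain boundary. Concentration is the superposition
`sum q (2 pi s)^(-3/2) exp(-|x - p|^2 / 2 s)` — the normalisation constant
is fixed in config; only relative concentrations matter to the controller.
Wind is a mean vector plus a first-order autoregressive (coloured)
perturbation (`wind_corr` per-tick autocorrelation, variance-matched for
arbitrary `dt`), optionally modulated by a smooth spatial term. The plume
has its own private RNG stream, so agent randomness and plume randomness
are independently reproducible. No parameter values are inherited from any
reference dataset: the defaults (release 0.5/tick, mean wind 0.05
units/tick, growth 0.002/tick, initial squared radius 0.5) were chosen once
to produce an intermittent but trackable plume at the package's world
scale, and are all exposed in `plume_params()`.

## Controllers

**Path integration.** A noise-free, clipped-linear CX circuit: two TN2
speed cells (preferred axes +/-45 degrees), an 8-column TB1 heading ring
(`(1 + cos(h - dir_i)) / 2`), 16 CPU4 memory cells integrating TN2 gated by
`(1 - TB1)` (gain 0.0025 per unit speed, no decay by default, clamped to
[0, 1] around a 0.5 baseline) and 16 CPU1 steering cells comparing the
memory, shifted one column, against the heading ring. The comparison is a
gated product (memory excitation, heading-ring inhibition), whose summed
left-minus-right difference is proportional to the sine of the angle
between stored home direction and heading: zero when aligned or opposed,
maximal at +/-90 degrees. The motor coupling is
`theta = kPI (sum left CPU1 - sum right CPU1)` with `kPI = 10` (chosen so
typical memory amplitudes saturate turns when far off-course), and the hip
swing follows the speed-modulation rule `Sl = Sl0 + Slf (1 - min(|theta|,
1))` with `Sl0 = 5`, `Slf = 20` degrees — confining `Sl` to [5, 25]
degrees. `decode_home_vector()` folds the two CPU4 banks, removes the mean
and reads phase/amplitude; on 200-step random routes it agrees with the
displacement-sum oracle to within a couple of degrees. The embodied loop
feeds the controller ground-truth heading and per-cycle displacement, as
the reference implementation did via its simulation supervisor.

**Visual beaconing.** Eye images are binarised; `delta` is the horizontal
distance from the image centre to the mean landmark column (the literal
width-referenced variant is available behind `form = "width"`; the
centre-based form follows the method's own textual definition). The
desired heading is the current heading encoding copied and shifted by
`ceiling(|6 delta / W|)` 45-degree columns toward the landmark, and the
steering circuit converts it to `theta` with motor scale `kvb = 0.25` —
chosen so the minimum one-column shift commands a ~10 degree/cycle turn,
i.e. a converging pursuit rather than a bang-bang oscillation. Monocular
agents use one eye; binocular agents average the per-eye `delta` over the
eyes that detect the landmark. With no detection the previous command is
held; before the first detection the agent turns in a random direction
(a fixed direction would bias the two monocular modes differently).

**Visual compass.** The panorama is mapped to the unit disk (zenith at the
centre) and the Zernike coefficient of order 7, repetition 1 is computed;
its phase is a rotational signature of the view. The controller compares
the current phase against the stored initial phase: `theta` is the sign of
the wrapped difference and `Sl = |difference| / 5`. The phase difference is
in radians, and the source material states hip swing in radians in its gait
definitions while using degrees elsewhere; we return the literal
radian-valued `Sl` from `visual_compass_step()` and convert to degrees at
the gait boundary in the scenario runner. Featureless panoramas
(coefficient magnitude below 1e-9) hold the previous command.

**Trail following.** Odour is sensed when either antenna reads at least
`To = 900`. Sensed and nearly balanced (`|Ol - Or| < 5`): straight, `Sl =
8`. Sensed and lateralised: `theta = (Ol - Or) / 400` (clipped to [-1, 1]
at the gait), `Sl = 4`. Not sensed: random cast `theta = +/-1`, `Sl = 3`.
The two published "sensed" columns overlap as printed; they are read as
`|Od| < Td` versus `|Od| >= Td`.

**Plume tracking.** Below the detection threshold `Top = 1e-6` the agent
searches in place (`theta = +/-1` random, `Sl = 5`). On detection it reads
the wind on the higher-concentration side, computes the upwind bearing with
a two-argument arctangent of the negated wind vector (the one-argument form
is quadrant-ambiguous), turns toward it (`theta = sign(delta)`,
`Sl = min(5 + |delta| mod 5, 15)` with `delta` wrapped to (-180, 180]
degrees — the `min` is inactive for this literal form, retained anyway) and
then surges straight (`Sl = 15`, `theta = 0`) for two gait loops before
re-sensing.

## Scenario conditions

All scenarios run tripod FK gait at `Sn = 5`, are seeded and bit-for-bit
reproducible, and log one tibble row per gait cycle. Completion radii
default to one body length (4 model units) except where noted.

* **Path integration**: start at the origin, initial heading uniform on
  [0, 2 pi); outbound = 60 cycles of a correlated random walk (heading
  noise 0.15 rad/step, smoothed) at `Sl = 15`; homing under CX control for
  up to 200 cycles. Success: approach within 10% of the outbound path
  length.
* **Visual beacon**: dark cylinder (radius 3) 20 units away at bearing
  pi/2 — subtending ~17 degrees, the classic landmark-approach proportion.
  Initial headings: left-eye agents uniform on [0, pi/2], right-eye on
  [pi/2, pi], binocular on [pi/4, 3 pi/4].
* **Visual compass**: ring of seeded landmarks 15-30 units out; the world
  rotates incrementally (1 degree/cycle) or jumps (90 degrees at cycle
  10); the error band is measured after a settling period.
* **Trail following**: start at (5, 0) heading pi; trail width 2 (widened:
  5), arc length 14, heading-noise curvature 0.4 — curved enough that
  trail-keeping genuinely requires the bilateral sensors; the trail shape
  varies per trial (trail seed = scenario seed).
* **Plume tracking**: source at the origin, mean wind +x at 0.05
  units/tick, agent starts 25 units downwind near the centerline heading
  upwind-ish; the plume is pre-evolved for 800 ticks; goal radius 3.

## What the synthetic worlds do and do not show

The generators emulate the *structure* of the reference experiments —
silhouette landmarks, floor-painted trails, filament plumes in meandering
wind — not their photometric or aerodynamic detail. Passing tests
demonstrate that the controllers close their sensorimotor loops under
idealised, noise-controlled sensing with ground-truth self-motion signals.
They do not demonstrate robustness to real imagery, lighting, sensor
noise, slip or contact dynamics, and absolute times/speeds are not
comparable to any physics-based or hardware result — only orderings and
rates are asserted.

## Numerical choices and degenerate inputs

Headings are wrapped to (-pi, pi] everywhere; `sign(0)` is 0 in every
controller; steering commands outside [-1, 1] are clipped (the yaw-control
table warns; scenario runners clip silently before the gait); law-of-cosine
arguments are clamped to [-1, 1] against rounding; a zero-length outbound
route homes immediately at the nest; empty masks, featureless panoramas and
odour-free sensing all fall back to explicit hold/search behaviour rather
than erroring. Problem sizes in the test suite (route lengths, seed counts,
cycle budgets) are chosen so the full suite exercises every closed loop in
a few minutes on a laptop.

## Known limitations

No contact dynamics, terrain, adhesion or torque signals; no compound-eye
optics; antennal sweep kinematics are assumptions; the CX model is the
minimal noise-free variant (no ring-attractor dynamics, no sigmoid/noise
mode beyond the hooks in `cx_state()`); plume parameters are
self-calibrated rather than fitted; IK-mode gaits support the same
schedules as FK but the navigation scenarios drive the FK gait only.
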