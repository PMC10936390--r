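---
title: "Methods: gait monitoring, margin of stability, and robot-guided walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait monitoring, margin of stability, and robot-guided walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmos)
```

gaitmos analyses overground walking recorded by a portable system: a pair of
sensorised insoles (eight force-sensitive resistor cells, FSR, plus a
6-axis IMU per foot, ~100 Hz) and a differential-drive guide robot whose
rear-facing depth camera tracks the walker's pelvis and feet (~30 Hz, with
dropout). This vignette documents the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open.

## The synthetic walking generator

Every estimator in the package is exercised against `simulate_walk()`,
which produces ground-truth kinematics *and* the noisy sensor streams a
real recording would give.

**What it emulates.** Each foot alternates stance and swing. Stride times
and stride lengths are drawn per stride as
$\mathrm{ST}_k = \mathrm{ST}_0(1 + \mathrm{cv}\,z_k)$ with $z_k$ standard
normal, and placements advance by the drawn stride length along a straight
line; feet are offset laterally by half the step width. Swing follows a
minimum-jerk (quintic) profile between placements with a configurable peak
clearance (default 0.05 m) and a $C^2$ vertical bump, so the analytic
second derivative of the trajectory is available exactly. The defaults are
the walking pattern of a community-dwelling older adult on a guided walk:
stride length 1.12 m, stride time 1.17 s, step width 0.09 m, swing percent
35.11%, stride-to-stride CV 3% (a typical magnitude for older adults; the
between-subject spreads reported for such cohorts are wider and are not a
stride-to-stride quantity).

The insole load during stance is two raised-cosine bumps (heel, then
forefoot) on top of a constant weight-acceptance pedestal, summing to the
body-weight scale at its peaks and exactly zero during swing. The pedestal
makes the load step sharply at heel strike and toe off; with a purely
raised-cosine onset the threshold crossing would trail the true contact by
tens of milliseconds, which is not how a heel strikes a floor.

The IMU reads the analytic second derivative of the foot trajectory
expressed in the sensor frame plus gravity plus white noise; during stance
the foot is exactly stationary, so the true specific-force magnitude equals
$g$ and the true angular rate is zero. Camera fixes are the true poses
subsampled at the camera rate (with a sub-period jitter emulating an
unsynchronised clock), expressed in the camera frame through the robot pose
and extrinsics, with additive Gaussian noise and Bernoulli dropout.

**What it does not emulate.** The foot does not rotate (no heel-to-toe
pitch), there is no soft-tissue artefact, no IMU bias or scale error, no
camera outliers or latency, and the path is straight. Sensor noise
magnitudes (accelerometer 0.05 m/s², gyroscope 0.01 rad/s, camera 0.01 m,
10% dropout) are order-of-magnitude engineering defaults, configurable per
trial, since the hardware's true figures are not published. Passing tests
therefore demonstrate algorithmic correctness under a faithful signal
*structure*, not robustness to every artefact of real hardware.

**Determinism.** One integer seed drives the generator; sub-streams
(kinematics, per-foot IMU noise, camera) use fixed seed offsets, so
identical configurations reproduce byte-identical trials.

## Event detection and temporal parameters

Heel strike (HS) and toe off (TO) are threshold crossings of the summed
FSR channels: HS at an upward crossing of `threshold + hysteresis/2`, TO at
a downward crossing of `threshold - hysteresis/2`. The crossing time is the
timestamp of the first sample beyond the level — no sub-sample
interpolation, matching the data's native granularity. Candidate stance or
swing intervals shorter than 0.1 s are treated as chatter: short swing gaps
are merged first, then short stance islands dropped.

The threshold in the original deployment was determined empirically and its
value is not recoverable; the default here is a self-scaling rule — 5% of
the trial's 95th-percentile total load, with a 1% hysteresis band — so
synthetic units, raw ADC counts, and Newtons all work unchanged, and
detection is invariant to a joint rescaling of channels and threshold.

Stride time is the interval between consecutive same-foot heel strikes,
swing time the interval from toe off to the next heel strike, and swing
percent their ratio times 100. On noiseless synthetic trials every detected
event lands within one sample period (10 ms at 100 Hz) of ground truth, and
derived quantities inherit exactly that quantisation: stride velocity, for
instance, can deviate by up to $\mathrm{SV}\cdot\Delta t/\mathrm{ST}
\approx 8$ mm/s even when stride length is recovered sub-millimetre.

## The foot-pose EKF

Spatial parameters need foot positions, which neither sensor gives alone:
the IMU drifts and the camera is intermittent. `run_ekf()` fuses them in an
error-state extended Kalman filter with a 9-dimensional error state
(position, velocity, orientation error); the unit quaternion (Hamilton
convention, sensor-to-world) is kept outside the covariance. Accelerometer
and gyroscope biases are omitted: trials last minutes and camera fixes
bound drift; the configuration reserves noise parameters should biases be
added.

Prediction integrates the strapdown equations with trapezoidal averaging of
the two IMU samples bracketing each step; with endpoint-only integration
the velocity error grows like $\tfrac{\Delta t}{2}\,a(t)$, which at
mid-swing accelerations of 10–20 m/s² is a centimetre-level position lag —
visible against the sub-millimetre accuracy the rest of the chain achieves.
Camera fixes are applied at their exact timestamps by splitting the predict
step, not snapped to the nearest IMU sample: at 4 m/s mid-swing foot speed,
a 5 ms timestamp mismatch is a 2 cm innovation error. Updates use the
Joseph form, and the covariance is symmetrised each step; a test asserts
symmetric positive semi-definiteness through fused runs.

**Foot-flat and ZUPT.** Foot-flat (FF) is detected where the normalised
acceleration satisfies $\left|\,\lVert a\rVert/g - 1\,\right| < 0.05$ *and*
$\lVert\omega\rVert < 0.5$ rad/s for at least 0.1 s. The angular-rate gate
is standard practice in the zero-velocity-update literature and guards
against gravity-magnitude coincidences during slow swings. Inside FF a
zero-velocity pseudo-measurement (SD 0.01 m/s) is applied each step, which
keeps dead-reckoning bounded when the camera drops out.

**Spatial definitions.** Stride length is the horizontal distance between
the filtered positions at midpoints of consecutive same-foot FF intervals —
the midpoint minimises contamination from loading/unloading transients,
since the instant within FF is otherwise arbitrary. Stride velocity is
SL/ST. Step width is the lateral distance from a foot's FF position to the
line through the two flanking contralateral FF positions — the standard
step-width construction, adopted here because the deployment's computation
is not described. Strides without flanking FF anchors are flagged and
excluded rather than extrapolated.

## Margin of stability

The walker is modelled as an inverted pendulum of length $l$ (the recorded
leg length): $\omega_0 = \sqrt{g/l}$, and the extrapolated centre of mass
is

$$\mathrm{XCoM} = \mathrm{CoM} + \dot{\mathrm{CoM}}/\omega_0 .$$

The CoM is the pelvis track projected to the ground plane, smoothed by a
0.15 s moving average and differentiated by centred differences; gaps up to
0.5 s are interpolated, longer gaps stay missing. Whether the deployment
offset the pelvis point to an anatomical CoM estimate is unstated; the
projection is used as-is.

The base of support (BoS) is the convex hull of the in-contact feet's
outline vertices — an 8-vertex convex sole template scaled from shoe
length, placed at each foot's planar pose. Contact comes from the insole
load (the most direct contact measure), not from camera data. The margin of
stability is the signed distance from XCoM to the BoS boundary, positive
inside.

**AP/ML projection.** Projecting a scalar signed distance onto axes is
ambiguous. The package computes *directional margins*: the distance from
XCoM to the BoS boundary measured along the anteroposterior axis and along
the mediolateral axis separately (boundary-crossing distances, positive
towards the interior; when the axis line misses the polygon entirely the
signed Euclidean distance is used as a conservative fallback). The AP axis
is the mean CoM-velocity direction over the gait cycle; ML is its left
perpendicular, so all margins are equivariant under rigid motions of the
world frame (asserted to 1e-9).

Each cycle (heel strike to next heel strike) is resampled by linear
interpolation onto 100 equally spaced phase points. The cycle scalars are
the mean AP margin and the integrals over normalised phase of the positive
and negative parts of the ML margin, computed as means over the 100 phase
samples (a Riemann sum on the phase grid, which reproduces piecewise
profiles exactly). Whether the original analysis integrated over phase
(units m) or over time (units m·s) is unstated; phase is the default and
`integrate_time = TRUE` switches.

## The guidance simulator

The robot is a unicycle,
$\dot x = v\cos\theta,\ \dot y = v\sin\theta,\ \dot\theta = \omega$,
stepped *exactly*: a straight segment when $\omega = 0$, otherwise a
circular arc of radius $v/\omega$ — so results are insensitive to the 0.05 s
control period (verified against fine Euler integration). The walking track
is the 38 m oval used in the guided-walking protocol: two 13 m straights
and 1.91 m semicircular caps. The robot path defaults to the human path
itself (zero inward offset): a follower at distance $d_r$ along the same
path sits on the rear camera axis, which is the field-of-view design goal;
an inward offset remains available.

**Distance keeping.** With the robot leading, the measured distance grows
when the robot accelerates, so the stable PI law is on $e = d_r - d$:

$$v_{PI} = \mathrm{clamp}\!\left(K_p\,e + K_i \int e\,dt,\ 0,\ v_{max}\right),$$

the robot slowing (to a halt) when the walker lags and speeding up when the
walker closes in. The closed loop $\ddot\varepsilon + K_p\dot\varepsilon +
K_i\varepsilon = 0$ is then strictly stable; the opposite sign is a
positive feedback loop and diverges. The published gains are not
recoverable; defaults are $d_r = 1.5$ m (within depth-camera body-tracking
range), $K_p = 1$ s⁻¹, $K_i = 0.2$ s⁻², giving closed-loop time constants
of roughly 1.4 s and 3.6 s. The integrator is clamped at $v_{max}/K_i$
(anti-windup). The planner is pure pursuit toward a 0.6 m lookahead — a
stand-in for a full local planner — and its command is rescaled to the PI
speed as $(v_{PI},\ \omega\,v_{PI}/v)$, which preserves the commanded
curvature $\omega/v$ exactly and hence the tracked path.

On the straights the Euclidean robot–human distance equals the path
separation and the loop converges to zero error; on the 1.91 m end caps the
chord of a 1.5 m arc separation is 1.462 m, so a bounded ~4 cm geometric
transient appears at each cap entry and exit. Speed-matching assertions are
therefore made on a straight track, while the oval run is required to hold
the distance within 5 cm after convergence. Error metrics (MAE and error
SD of distance and of robot-vs-human speed) exclude the first 15 s and last
5 s of a run as controller transients.

## Cohort statistics

Per-trial summaries are the mean and the coefficient of variation
(CV = 100·SD/mean, sample SD with the $n-1$ denominator — the convention is
not stated in the source analysis) of each gait metric over the pooled
strides. Dual-task contrasts are per-metric differences (D − N) and ratios
(D / N); ratios with a near-zero normal-walking denominator are flagged
undefined rather than returned as infinities.

Hierarchical regression fits ordinary least squares with base predictors
age and gender (coded 0/1) and adds SPPB or MoCA in the complete model,
reporting $R^2$ for both, $\Delta R^2$, unstandardised coefficients with
95% t-intervals, standardised coefficients via z-scored variables, and
per-coefficient p-values. No multiple-testing correction is applied by
default, matching the per-model reporting style of the original analysis;
`regression_table(adjust_p = TRUE)` applies Benjamini–Hochberg.

**Power analysis.** `detectable_effect_size()` solves for the smallest
Cohen's $f^2$ at which the omnibus F-test (numerator df $u$, denominator df
$v = n-u-1$) reaches the target power, by root-finding on the power of the
noncentral F distribution — strictly increasing in $f^2$, so the root is
unique. The noncentrality convention is genuinely ambiguous across
software: with $\lambda = f^2 n$ the design $n=22$, $u=3$, $\alpha=0.05$,
power 0.8 gives $f^2 = 0.617$; with $\lambda = f^2(u+v) = f^2(n-1)$ it
gives $f^2 = 0.646$, which rounds to the 0.65 reported for this study
design. The package defaults to the $u+v$ multiplier — the convention under
which the published sensitivity analysis is internally consistent — and
exposes `ncp = "n"` for the other.

## Problem sizes and numerical choices

Tests and the acceptance script use 8-stride trials for unit-level checks
and 40-stride trials (the length of a four-lap guided walk) for
accuracy benchmarks; geometric properties are checked on 10⁴ random
convex-polygon cases against a brute-force oracle (edge-wise 1-D
minimisation plus ray casting). Signed-distance agreement is required to
1e-9; EKF covariances are symmetrised each step and checked PSD to 1e-10;
polygon inward normals are oriented by signed area; degenerate inputs
(fewer than three distinct polygon vertices, zero-support samples, strides
without FF anchors, empty camera streams) are rejected or flagged rather
than silently patched.

## Known limitations

* The generator's straight-line path means turning gait and its
  asymmetries are untested; the estimators themselves carry no
  straight-line assumption.
* Identity foot orientation in the generator leaves the EKF's orientation
  error states only lightly exercised (they are driven by gyro noise, not
  by real rotation profiles).
* The camera model has Gaussian noise and dropout but no outliers; a real
  body tracker occasionally produces gross errors that would need gating.
* Margins of stability depend on the foot-outline template; absolute ML/AP
  margin values shift with outline size, while contrasts between
  conditions are far less sensitive.
* The guidance simulator models the human as a point following the path
  exactly; lateral wander within the lane is not simulated.
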