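# gaitmos

Quantitative gait analysis for robot-guided overground walking in older
adults, from a portable sensor pair: **instrumented insoles** (eight
force-sensitive resistor cells + a 6-axis IMU per foot, ~100 Hz) and a
mobile guide robot whose rear-facing depth camera tracks the walker's
pelvis and feet (~30 Hz, with dropout). The package is aimed at movement
scientists and rehabilitation engineers who want laboratory-grade
spatiotemporal gait parameters and dynamic balance measures outside the
lab, plus the statistics used to relate them to physical performance
(SPPB) and cognition (MoCA).

## What it computes

* **Gait events and temporal parameters** — heel strike (HS) and toe off
  (TO) from hysteresis threshold crossings of the summed insole load;
  stride time ST, swing time, swing percent SwP.
* **Spatial parameters by sensor fusion** — an error-state extended Kalman
  filter fuses strapdown IMU prediction with camera position fixes and
  zero-velocity updates (ZUPT) during detected foot-flat (FF):
  stride length SL = distance between consecutive same-foot FF positions,
  stride velocity SV = SL/ST, and step width SW.
* **Dynamic margin of stability** — with the inverted-pendulum
  extrapolated centre of mass
  `XCoM = CoM + v_CoM / ω₀`, `ω₀ = √(g/l)`, and the base of support (BoS)
  as the convex hull of the in-contact foot outlines, the margin of
  stability (MoS) is the signed distance from XCoM to the BoS boundary
  (positive inside). Each gait cycle is time-normalised to 100 phase
  points and summarised as MoS_AP (mean anteroposterior margin) and
  MoS_ML± (phase-integrals of the positive/negative mediolateral margin).
* **Robot distance-keeping simulation** — exact unicycle kinematics, a PI
  controller on the human–robot distance error `e = d_r − d`,
  `v_PI = clamp(K_p e + K_i ∫e dt, 0, v_max)`, and curvature-preserving
  scaling `(v_PI, ω·v_PI/v)` of a pure-pursuit command on the 38-m oval
  walking track; evaluation by MAE and error SD after excluding the first
  15 s and last 5 s.
* **Cohort statistics** — per-trial means and coefficients of variation,
  dual-task (D − N, D/N) contrasts, hierarchical linear regression with
  ΔR², and the detectable-effect-size power analysis for a
  three-predictor model.
* **A synthetic walking generator** — ground-truth kinematics with
  configurable variability, sensor noise, and camera dropout, so the whole
  chain is testable without hardware.

## Worked example

```r
library(gaitmos)

trial  <- simulate_walk(gait_sim_config(n_strides = 12, seed = 42))
report <- run_pipeline(trial)
report
#> <gait_report> 24 strides, 50 events
#> # A tibble: 18 × 5
#>    foot  metric         n    mean     cv
#>    <chr> <chr>      <int>   <dbl>  <dbl>
#>  1 left  st            12  1.20    2.60
#>  2 left  swing         12  0.419   2.96
#>  3 left  swp           12 35.0     0.874
#>  4 left  sl            12  1.12    3.14
#>  5 left  sv            12  0.935   3.75
#>  6 left  sw            11  0.0893  3.60
#>  7 left  mos_ap        11 -0.126  69.2
#>  8 left  mos_ml_pos    11  0.0137 39.1
#>  9 left  mos_ml_neg    11 -0.181  40.7
#> # … and the right foot rows
```

One row per metric per foot: `mean` in SI units (s, m, m/s; `swp` in
percent) and `cv` the stride-to-stride coefficient of variation in
percent. The recovered means match the simulated gait (stride length
1.12 m, stride time 1.17 s, step width 0.09 m, swing percent ~35%), and
the CVs sit near the configured 3% stride-to-stride variability. The
negative mean `mos_ap` says the extrapolated centre of mass travels ahead
of the base of support for much of the cycle — the usual "controlled
falling" picture of forward walking — while `mos_ml_pos`/`mos_ml_neg`
split the mediolateral margin into its stable and unstable parts.

```r
error_metrics(simulate_guided_walk(build_paths(), human_speed = 1.0,
                                   duration = 120, seed = 42))
#> # A tibble: 1 × 4
#>   mae_distance esd_distance mae_velocity esd_velocity
#>          <dbl>        <dbl>        <dbl>        <dbl>
#> 1      0.00569      0.00855      0.00498      0.00840
```

After the transients, the simulated robot holds the desired 1.5 m
distance to within centimetres of MAE and matches the walker's speed.

```r
detectable_effect_size(n = 22, alpha = 0.05, power = 0.8, u = 3)
#> [1] 0.6463177
```

The smallest Cohen's f² detectable at 80% power with three predictors and
22 participants — a moderate-to-large effect, ~0.65.

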