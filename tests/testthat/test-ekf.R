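# Foot-flat detection, EKF steps, fusion, and spatial parameters.

test_that("foot-flat detection covers a stationary stream and rejects a moving one", {
  g <- 9.81
  t <- seq(0, 10, by = 0.01)
  still <- tibble::tibble(t = t, foot = "left", ax = 0, ay = 0, az = g,
                          gx = 0, gy = 0, gz = 0)
  iv <- detect_foot_flat(still)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$t_start, 0)
  expect_equal(iv$t_end, 10)
  moving <- dplyr::mutate(still, az = 1.5 * g)
  expect_equal(nrow(detect_foot_flat(moving)), 0)
  expect_equal(nrow(detect_foot_flat(still[0, ])), 0)
})

test_that("detected foot-flat intervals contain every truth foot-flat midpoint", {
  tr <- noiseless_trial()
  for (f in c("left", "right")) {
    iv <- detect_foot_flat(tr[[paste0("insole_", f)]])
    truth <- tr$truth$ff[tr$truth$ff$foot == f, ]
    mids <- (truth$t_start + truth$t_end) / 2
    inside <- vapply(mids, function(m) {
      any(iv$t_start <= m & iv$t_end >= m)
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("prediction at rest under gravity leaves position and velocity unchanged", {
  cfg <- ekf_config()
  st <- ekf_state()
  st2 <- ekf_predict(st, c(0, 0, cfg$g), c(0, 0, 0), 0.01, cfg)
  expect_equal(st2$p, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(st2$v, c(0, 0, 0), tolerance = 1e-12)
  expect_gt(sum(diag(st2$P)), sum(diag(st$P))) # covariance grows
})

test_that("prediction with zero specific force is the ballistic closed form", {
  cfg <- ekf_config()
  st <- ekf_state(v = c(1, 0, 0))
  dt <- 0.01
  st2 <- ekf_predict(st, c(0, 0, 0), c(0, 0, 0), dt, cfg)
  expect_equal(st2$p, c(dt, 0, -0.5 * cfg$g * dt^2), tolerance = 1e-12)
  expect_equal(st2$v, c(1, 0, -cfg$g * dt), tolerance = 1e-12)
})

test_that("stationary dead reckoning does not drift", {
  cfg <- ekf_config()
  st <- ekf_state()
  for (i in 1:1000) st <- ekf_predict(st, c(0, 0, cfg$g), c(0, 0, 0), 0.01, cfg)
  expect_lt(sqrt(sum(st$p^2)), 1e-9)
  expect_psd(st$P)
})

test_that("non-finite IMU input is a numeric error", {
  expect_error(ekf_predict(ekf_state(), c(NA, 0, 0), c(0, 0, 0), 0.01),
               class = "gaitmos_numeric_error")
  expect_error(ekf_predict(ekf_state(), c(0, 0, 0), c(0, 0, 0), 0),
               class = "gaitmos_numeric_error")
})

test_that("camera update obeys the measurement-dominated and zero-innovation limits", {
  cfg <- ekf_config(cam_pos_noise_sd = 1e-6)
  st <- ekf_state(P = diag(c(rep(100, 3), rep(1, 3), rep(0.01, 3))))
  fix <- list(x = 1, y = 0, z = 0, valid = TRUE)
  pose <- list(x = 0, y = 0, theta = 0)
  st2 <- ekf_update_camera(st, fix, pose, config = cfg)
  expect_equal(st2$p, c(1, 0, 0), tolerance = 1e-6)
  expect_psd(st2$P)

  # fix equal to the prior mean: mean unchanged, covariance shrinks
  cfg2 <- ekf_config(cam_pos_noise_sd = 0.05)
  st3 <- ekf_state(p = c(2, 3, 0))
  fix3 <- list(x = 2, y = 3, z = 0, valid = TRUE)
  st4 <- ekf_update_camera(st3, fix3, pose, config = cfg2)
  expect_equal(st4$p, c(2, 3, 0), tolerance = 1e-12)
  expect_lt(sum(diag(st4$P[1:3, 1:3])), sum(diag(st3$P[1:3, 1:3])))

  # invalid fix is a no-op
  expect_message(st5 <- ekf_update_camera(st3, list(x = 9, y = 9, z = 9, valid = FALSE),
                                          pose, config = cfg2),
                 class = "gaitmos_skip")
  expect_equal(st5$p, st3$p)
})

test_that("the camera fix is mapped through robot pose and extrinsics", {
  cfg <- ekf_config(cam_pos_noise_sd = 1e-6)
  st <- ekf_state(P = diag(c(rep(100, 3), rep(1, 3), rep(0.01, 3))))
  # robot at (1,2) heading pi/2: sensor point (1,0,0) -> world (1,3,0)
  fix <- list(x = 1, y = 0, z = 0, valid = TRUE)
  pose <- list(x = 1, y = 2, theta = pi / 2)
  st2 <- ekf_update_camera(st, fix, pose, config = cfg)
  expect_equal(st2$p, c(1, 3, 0), tolerance = 1e-6)
})

test_that("zero-velocity update pulls velocity to zero and is exact at zero innovation", {
  cfg <- ekf_config(zupt_noise_sd = 1e-6)
  st <- ekf_state(v = c(0.3, 0, 0))
  st2 <- ekf_update_zupt(st, cfg)
  expect_lt(sqrt(sum(st2$v^2)), 1e-3)
  st0 <- ekf_state(v = c(0, 0, 0))
  st3 <- ekf_update_zupt(st0, cfg)
  expect_equal(st3$v, c(0, 0, 0), tolerance = 1e-15)
  expect_equal(st3$p, st0$p, tolerance = 1e-15)
})

test_that("covariance stays symmetric PSD through a fused run", {
  tr <- noiseless_trial()
  cfg <- ekf_config()
  st <- ekf_state()
  set.seed(1)
  for (i in 1:50) {
    st <- ekf_predict(st, rnorm(3, c(0, 0, 9.81), 0.05), rnorm(3, 0, 0.01),
                      0.01, cfg)
    if (i %% 10 == 0) {
      st <- ekf_update_camera(st, list(x = st$p[1], y = st$p[2], z = st$p[3],
                                       valid = TRUE),
                              list(x = 0, y = 0, theta = 0), config = cfg)
    }
    if (i %% 7 == 0) st <- ekf_update_zupt(st, cfg)
    expect_equal(st$P, t(st$P), tolerance = 1e-12)
    expect_psd(st$P)
  }
})

test_that("noiseless fusion recovers the true trajectory to under a millimetre", {
  tr <- noiseless_trial()
  fused <- fused_noiseless()
  for (f in c("left", "right")) {
    traj <- if (f == "left") fused$traj_left else fused$traj_right
    truth <- tr$truth[[paste0("foot_", f)]]
    err <- sqrt((traj$x - truth$x)^2 + (traj$y - truth$y)^2 +
                  (traj$z - truth$z)^2)
    expect_lt(max(err), 1e-3)
  }
})

test_that("spatial parameters match the generator truth on a noiseless walk", {
  tr <- noiseless_trial()
  fused <- fused_noiseless()
  cmp <- dplyr::inner_join(fused$strides, tr$truth$strides,
                           by = c("foot", "stride"), suffix = c("", ".tr"))
  expect_true(all(abs(cmp$sl - cmp$sl.tr) < 1e-3, na.rm = TRUE))
  # SV = SL/ST inherits the one-sample quantisation of the detected stride
  # time: |dSV| <= SV * dt / ST ~ 8e-3 at 100 Hz
  expect_true(all(abs(cmp$sv - cmp$sv.tr) < 1e-2, na.rm = TRUE))
  expect_true(all(abs(cmp$sw - cmp$sw.tr) < 5e-3, na.rm = TRUE))
  expect_equal(cmp$st, cmp$st.tr, tolerance = 0.011) # one FSR sample
})

test_that("stride length and step width follow their definitions", {
  # two stances at (0,0) and (1.12,0), stride time 1.17 s
  mk_traj <- function(pts, ts) {
    tibble::tibble(t = ts, x = pts[, 1], y = pts[, 2], z = 0,
                   vx = 0, vy = 0, vz = 0, qw = 1, qx = 0, qy = 0, qz = 0,
                   trace_P = 0)
  }
  traj_l <- mk_traj(rbind(c(0, 0.05), c(0, 0.05), c(1.12, 0.05), c(1.12, 0.05)),
                    c(0, 0.4, 1.17, 1.57))
  traj_r <- mk_traj(rbind(c(-0.56, -0.05), c(-0.56, -0.05), c(0.56, -0.05),
                          c(0.56, -0.05)),
                    c(-0.6, -0.2, 0.6, 1.0))
  ff_l <- tibble::tibble(foot = "left", t_start = c(0, 1.17),
                         t_end = c(0.4, 1.57))
  ff_r <- tibble::tibble(foot = "right", t_start = c(-0.6, 0.6),
                         t_end = c(-0.2, 1.0))
  strides <- tibble::tibble(foot = "left", stride = 1L, t_hs = 0, t_to = 0.5,
                            t_next_hs = 1.17, st = 1.17, swing = 0.67,
                            swp = 57.3, sl = NA_real_, sv = NA_real_,
                            sw = NA_real_)
  out <- spatial_parameters(strides, traj_l, traj_r, ff_l, ff_r)
  expect_equal(out$sl, 1.12, tolerance = 1e-9)
  expect_equal(out$sv, 1.12 / 1.17, tolerance = 1e-9)
  expect_equal(round(out$sv, 5), 0.95726)
  expect_equal(out$sw, 0.10, tolerance = 1e-9)
})

test_that("a stride without flanking foot-flat is excluded, not guessed", {
  traj <- tibble::tibble(t = c(0, 1), x = 0, y = 0, z = 0, vx = 0, vy = 0,
                         vz = 0, qw = 1, qx = 0, qy = 0, qz = 0, trace_P = 0)
  ff_empty <- tibble::tibble(foot = character(), t_start = numeric(),
                             t_end = numeric())
  strides <- tibble::tibble(foot = "left", stride = 1L, t_hs = 0, t_to = 0.5,
                            t_next_hs = 1, st = 1, swing = 0.5, swp = 50,
                            sl = NA_real_, sv = NA_real_, sw = NA_real_)
  expect_message(out <- spatial_parameters(strides, traj, traj, ff_empty,
                                           ff_empty),
                 class = "gaitmos_skip")
  expect_false(out$spatial_ok)
  expect_true(is.na(out$sl))
})

test_that("spatial estimates are invariant to a rigid world transform", {
  tr <- noiseless_trial()
  fused <- fused_noiseless()
  ang <- 0.7; shift <- c(5, -3)
  rot_traj <- function(traj) {
    xy <- rotate_xy(cbind(traj$x, traj$y), ang, shift)
    dplyr::mutate(traj, x = xy[, 1], y = xy[, 2])
  }
  out0 <- suppressMessages(spatial_parameters(
    temporal_parameters(fused$events), fused$traj_left, fused$traj_right,
    fused$ff_left, fused$ff_right))
  out1 <- suppressMessages(spatial_parameters(
    temporal_parameters(fused$events), rot_traj(fused$traj_left),
    rot_traj(fused$traj_right), fused$ff_left, fused$ff_right))
  expect_equal(out1$sl, out0$sl, tolerance = 1e-9)
  expect_equal(out1$sv, out0$sv, tolerance = 1e-9)
  expect_equal(out1$sw, out0$sw, tolerance = 1e-9)
})

test_that("ZUPT bounds drift when the camera drops out; without it drift grows", {
  tr <- noisy_trial()
  ins <- tr$insole_left
  cam <- tr$camera[tr$camera$target == "left_foot" & tr$camera$t < 3, ]
  cfg <- ekf_config()
  ff <- detect_foot_flat(ins, cfg)
  traj_zupt <- suppressMessages(run_ekf(ins, cam, tr$robot_pose, cfg, ff = ff))
  no_ff <- ff[0, ]
  traj_free <- suppressMessages(run_ekf(ins, cam, tr$robot_pose, cfg,
                                        ff = no_ff))
  truth <- tr$truth$foot_left
  err_z <- sqrt((traj_zupt$x - truth$x)^2 + (traj_zupt$y - truth$y)^2)
  err_f <- sqrt((traj_free$x - truth$x)^2 + (traj_free$y - truth$y)^2)
  late <- tr$insole_left$t > 3
  n_strides_late <- sum(tr$truth$strides$t_hs[tr$truth$strides$foot == "left"] > 3)
  # with ZUPT: bounded velocity drift, < 5 cm per stride overall
  expect_lt(max(err_z[late]), 0.05 * n_strides_late)
  expect_gt(max(err_f[late]), max(err_z[late]))
})

test_that("an empty camera stream degrades gracefully with a warning", {
  tr <- noiseless_trial()
  empty_cam <- tr$camera[0, ]
  expect_warning(
    traj <- suppressMessages(run_ekf(tr$insole_left, empty_cam,
                                     tr$robot_pose,
                                     ekf_config(cam_pos_noise_sd = 1e-4))),
    "IMU \\+ ZUPT")
  expect_equal(nrow(traj), nrow(tr$insole_left))
})

test_that("non-overlapping camera and insole streams are rejected", {
  tr <- noiseless_trial()
  cam <- tr$camera[tr$camera$target == "left_foot", ]
  cam$t <- cam$t + 1e5
  expect_error(run_ekf(tr$insole_left, cam, tr$robot_pose),
               "overlap", class = "gaitmos_input_error")
})
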