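# Margin-of-stability geometry and cycle summaries.

test_that("sensor-to-world transform matches pose arithmetic and inverts", {
  p <- c(1, 0, 0)
  id_pose <- list(x = 0, y = 0, theta = 0)
  expect_equal(as.numeric(sensor_to_world(p, id_pose)), p)
  pose <- list(x = 1, y = 2, theta = pi / 2)
  expect_equal(as.numeric(sensor_to_world(p, pose)), c(1, 3, 0),
               tolerance = 1e-12)
  # round trip world -> sensor -> world
  extr <- rigid_transform(quat_rot <- diag(3)[c(2, 1, 3), ] * c(1, -1, 1),
                          c(0.1, -0.2, 0.3))
  tf_pose <- gaitmos:::robot_pose_transform(pose$x, pose$y, pose$theta)
  w <- c(2.3, -1.1, 0.4)
  s <- gaitmos:::apply_rigid(gaitmos:::invert_rigid(extr),
                             gaitmos:::apply_rigid(gaitmos:::invert_rigid(tf_pose), w))
  expect_equal(as.numeric(sensor_to_world(as.numeric(s), pose, extr)), w,
               tolerance = 1e-12)
})

test_that("centre-of-mass estimation handles constant and linear motion", {
  t <- seq(0, 5, by = 1 / 30)
  still <- tibble::tibble(t = t, x = 1, y = 1, z = 1)
  com <- estimate_com(still)
  expect_equal(com$com_x, rep(1, length(t)))
  expect_equal(com$vcom_x, rep(0, length(t)))
  moving <- tibble::tibble(t = t, x = 0.98 * t, y = 0, z = 1)
  com2 <- estimate_com(moving)
  mid <- t > 0.5 & t < 4.5
  expect_equal(com2$vcom_x[mid], rep(0.98, sum(mid)), tolerance = 1e-9)
  expect_error(estimate_com(moving[1:3, ], smoothing = 0.5),
               class = "gaitmos_input_error")
})

test_that("smoothing reduces the velocity noise of a noisy linear track", {
  t <- seq(0, 10, by = 1 / 30)
  set.seed(42)
  noisy <- tibble::tibble(t = t, x = t + rnorm(length(t), 0, 0.005),
                          y = rnorm(length(t), 0, 0.005), z = 1)
  com <- estimate_com(noisy, smoothing = 0.2)
  raw_v <- diff(noisy$x) / diff(t)
  mid <- seq_along(t) > 10 & seq_along(t) < length(t) - 10
  rmse_smooth <- sqrt(mean((com$vcom_x[mid] - 1)^2))
  rmse_raw <- sqrt(mean((raw_v - 1)^2))
  expect_lt(rmse_smooth, rmse_raw)
})

test_that("xcom is the stated extrapolation and linear in velocity", {
  df <- tibble::tibble(com_x = 0, com_y = 0, vcom_x = 0.9, vcom_y = 0)
  body <- body_params(g = 9.0, leg_length = 1) # omega0 = 3
  out <- xcom(df, body)
  expect_equal(c(out$xcom_x, out$xcom_y), c(0.3, 0), tolerance = 1e-12)
  df2 <- tibble::tibble(com_x = 1, com_y = -1, vcom_x = 0, vcom_y = -0.6)
  body2 <- body_params(g = 4, leg_length = 1) # omega0 = 2
  out2 <- xcom(df2, body2)
  expect_equal(c(out2$xcom_x, out2$xcom_y), c(1, -1.3), tolerance = 1e-12)
  # zero velocity: identity; linearity in vcom
  df0 <- tibble::tibble(com_x = 2, com_y = 3, vcom_x = 0, vcom_y = 0)
  out0 <- xcom(df0, body)
  expect_identical(c(out0$xcom_x, out0$xcom_y), c(2, 3))
  dfa <- tibble::tibble(com_x = 0, com_y = 0, vcom_x = 1, vcom_y = 2)
  dfb <- tibble::tibble(com_x = 0, com_y = 0, vcom_x = 2, vcom_y = 4)
  expect_equal(2 * xcom(dfa, body)$xcom_x, xcom(dfb, body)$xcom_x)
})

test_that("base of support is the hull of in-contact outlines", {
  rect <- cbind(x = c(-0.125, 0.125, 0.125, -0.125),
                y = c(-0.05, -0.05, 0.05, 0.05))
  single <- bos_polygon(list(left = list(x = 0, y = 0, theta = 0),
                             right = NULL),
                        c(left = TRUE, right = FALSE), rect)
  expect_equal(nrow(single), 4)
  expect_equal(sort(single[, 1]), sort(rect[, 1]))

  # two unit squares at (0,0) and (2,0): hull is the 3 x 1 bounding rectangle
  sq <- cbind(x = c(-0.5, 0.5, 0.5, -0.5), y = c(-0.5, -0.5, 0.5, 0.5))
  both <- bos_polygon(list(left = list(x = 0, y = 0, theta = 0),
                           right = list(x = 2, y = 0, theta = 0)),
                      c(left = TRUE, right = TRUE), sq)
  expect_equal(nrow(both), 4)
  expect_equal(range(both[, 1]), c(-0.5, 2.5))
  expect_equal(range(both[, 2]), c(-0.5, 0.5))

  # duplicated vertices change nothing
  dup <- bos_polygon(list(left = list(x = 0, y = 0, theta = 0),
                          right = list(x = 0, y = 0, theta = 0)),
                     c(left = TRUE, right = TRUE), sq)
  expect_equal(abs(gaitmos:::polygon_area(dup)), 1, tolerance = 1e-12)

  expect_null(bos_polygon(list(left = NULL, right = NULL),
                          c(left = FALSE, right = FALSE), sq))
})

test_that("signed distance matches hand-computed square cases", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(signed_distance(c(0.5, 0.5), sq), 0.5, tolerance = 1e-12)
  expect_equal(signed_distance(c(1.5, 0.5), sq), -0.5, tolerance = 1e-12)
  expect_equal(signed_distance(c(1, 0.5), sq), 0, tolerance = 1e-12)
  expect_error(signed_distance(c(0, 0), sq[1:2, ]),
               class = "gaitmos_input_error")
})

test_that("signed distance agrees with the brute-force oracle on random cases", {
  set.seed(7)
  for (i in 1:400) {
    poly <- random_convex_polygon()
    pt <- runif(2, -1.5, 1.5)
    expect_equal(signed_distance(pt, poly), oracle_signed_distance(pt, poly),
                 tolerance = 1e-9)
  }
})

test_that("cycle summaries follow the phase-normalisation contract", {
  # constant margins over the cycle
  t <- seq(0, 1.2, by = 0.01)
  sq <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10))
  track <- tibble::tibble(
    t = t, com_x = t, com_y = 0, vcom_x = 1, vcom_y = 0,
    xcom_x = 0, xcom_y = 0, n_support = 1L, mos = 10,
    bos = replicate(length(t), sq, simplify = FALSE))
  cyc <- cycle_mos(track, list(t_hs = 0, t_next_hs = 1.2))
  expect_equal(nrow(cyc$phase_series), 100)
  expect_equal(cyc$mos_ap, 10, tolerance = 1e-9)
  expect_equal(cyc$heading, c(1, 0))

  # the phase series has exactly 100 samples at any input sampling rate
  for (rate in c(17, 30, 100)) {
    tt <- seq(0, 1.3, by = 1 / rate)
    trk <- tibble::tibble(
      t = tt, com_x = tt, com_y = 0, vcom_x = 1, vcom_y = 0,
      xcom_x = 0, xcom_y = 0, n_support = 1L, mos = 10,
      bos = replicate(length(tt), sq, simplify = FALSE))
    expect_equal(nrow(cycle_mos(trk, list(t_hs = 0, t_next_hs = 1.2))$phase_series),
                 100)
  }
})

test_that("piecewise-constant ML margins integrate to their halves", {
  # synthetic margin series fed through the same resampling path
  t <- seq(0, 1, by = 0.005)
  sq_in <- cbind(c(-1000, 1000, 1000, -1000), c(-0.1, -0.1, 1000, 1000))
  sq_out <- cbind(c(-1000, 1000, 1000, -1000), c(0.1, 0.1, 1000, 1000))
  track <- tibble::tibble(
    t = t, com_x = t, com_y = 0, vcom_x = 1, vcom_y = 0,
    xcom_x = 0, xcom_y = 0, n_support = 1L, mos = 1,
    bos = lapply(t, function(ti) if (ti < 0.5) sq_in else sq_out))
  cyc <- cycle_mos(track, list(t_hs = 0, t_next_hs = 1))
  # ML margin (along +y, then -y by symmetry of the construction):
  # inside square: +0.1; outside square: -0.1
  expect_equal(cyc$mos_ml_pos, 0.05, tolerance = 2e-3)
  expect_equal(cyc$mos_ml_neg, -0.05, tolerance = 2e-3)
  expect_gte(cyc$mos_ml_pos, 0)
  expect_lte(cyc$mos_ml_neg, 0)
})

test_that("cycle summary errors when the track does not cover the cycle", {
  t <- seq(0, 0.5, by = 0.01)
  sq <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  track <- tibble::tibble(t = t, com_x = t, com_y = 0, vcom_x = 1, vcom_y = 0,
                          xcom_x = 0, xcom_y = 0, n_support = 1L, mos = 1,
                          bos = replicate(length(t), sq, simplify = FALSE))
  expect_error(cycle_mos(track, list(t_hs = 0, t_next_hs = 1.2)),
               "cover", class = "gaitmos_input_error")
})

test_that("per-cycle margins are invariant to a rigid world transform", {
  tr <- noiseless_trial()
  fused <- fused_noiseless()
  pelvis <- tr$truth$com[, c("t", "x", "y")]
  pelvis$z <- tr$config$leg_length
  com <- estimate_com(pelvis)
  body <- body_params(tr$config$leg_length)
  track0 <- mos_track(com, fused$traj_left, fused$traj_right, fused$events,
                      body)
  strides <- fused$strides
  cyc0 <- summarize_mos_cycles(track0, strides)

  ang <- 1.1; shift <- c(-4, 2)
  rot_traj <- function(traj) {
    xy <- rotate_xy(cbind(traj$x, traj$y), ang, shift)
    # rotate the heading quaternion about z as well
    qrot <- c(cos(ang / 2), 0, 0, sin(ang / 2))
    qs <- t(apply(cbind(traj$qw, traj$qx, traj$qy, traj$qz), 1, function(q) {
      gaitmos:::quat_multiply(qrot, q)
    }))
    dplyr::mutate(traj, x = xy[, 1], y = xy[, 2],
                  qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4])
  }
  pel_rot <- pelvis
  xy <- rotate_xy(cbind(pelvis$x, pelvis$y), ang, shift)
  pel_rot$x <- xy[, 1]; pel_rot$y <- xy[, 2]
  track1 <- mos_track(estimate_com(pel_rot), rot_traj(fused$traj_left),
                      rot_traj(fused$traj_right), fused$events, body)
  cyc1 <- summarize_mos_cycles(track1, strides)
  expect_equal(cyc1$mos_ap, cyc0$mos_ap, tolerance = 1e-9)
  expect_equal(cyc1$mos_ml_pos, cyc0$mos_ml_pos, tolerance = 1e-9)
  expect_equal(cyc1$mos_ml_neg, cyc0$mos_ml_neg, tolerance = 1e-9)
})
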