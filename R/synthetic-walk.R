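#' Configuration for the synthetic walking-trial generator
#'
#' Defines the ground-truth gait pattern and the sensor models used by
#' [simulate_walk()]. Defaults emulate overground walking of a
#' community-dwelling older adult wearing sensorised insoles while following
#' a guide robot: stride length 1.12 m, stride time 1.17 s, step width
#' 0.09 m, swing percent 35.11%, with 3% stride-to-stride variability,
#' insoles sampled at 100 Hz and camera fixes at 30 Hz with 10% dropout.
#'
#' @param n_strides Number of complete strides generated per foot.
#' @param nominal_sl Mean stride length (m).
#' @param nominal_st Mean stride time (s).
#' @param nominal_sw Step width (m): lateral distance between the left and
#'   right lines of foot placements.
#' @param nominal_swp Swing percent: swing time as a percentage of stride
#'   time, in (0, 100).
#' @param cv_sl,cv_st Stride-to-stride coefficient of variation (percent) of
#'   stride length and stride time.
#' @param fsr_rate,imu_rate Insole sampling rates (Hz). The insole record
#'   carries pressure and inertial channels jointly, so the two must be equal.
#' @param cam_rate Camera fix rate (Hz).
#' @param imu_noise_sd Length-2 numeric `c(accel, gyro)`: white-noise SD of
#'   the accelerometer (m/s^2 per axis) and gyroscope (rad/s per axis).
#' @param cam_noise_sd SD of the additive camera position noise (m per axis).
#' @param cam_dropout_prob Probability that a camera fix for a given target
#'   is dropped (its `valid` flag set to `FALSE`).
#' @param leg_length Subject leg length (m); also used as the pelvis height.
#' @param clearance Peak swing-foot clearance (m).
#' @param body_weight_load Total insole load at full weight acceptance, in
#'   calibrated load units.
#' @param robot_distance Distance (m) at which the simulated guide robot
#'   leads the pelvis; defines the robot pose track used for frame
#'   transforms.
#' @param extrinsics [rigid_transform()] mapping camera-frame points into the
#'   robot frame.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(n_strides = 40,
                            nominal_sl = 1.12,
                            nominal_st = 1.17,
                            nominal_sw = 0.09,
                            nominal_swp = 35.11,
                            cv_sl = 3,
                            cv_st = 3,
                            fsr_rate = 100,
                            imu_rate = 100,
                            cam_rate = 30,
                            imu_noise_sd = c(accel = 0.05, gyro = 0.01),
                            cam_noise_sd = 0.01,
                            cam_dropout_prob = 0.1,
                            leg_length = 0.9,
                            clearance = 0.05,
                            body_weight_load = 700,
                            robot_distance = 1.5,
                            extrinsics = rigid_transform(),
                            seed = 1L) {
  check_number(n_strides, "n_strides", lower = 1)
  check_number(nominal_sl, "nominal_sl", lower = 0, strict_lower = TRUE)
  check_number(nominal_st, "nominal_st", lower = 0, strict_lower = TRUE)
  check_number(nominal_sw, "nominal_sw", lower = 0)
  check_number(nominal_swp, "nominal_swp", lower = 0, upper = 100,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(cv_sl, "cv_sl", lower = 0)
  check_number(cv_st, "cv_st", lower = 0)
  check_number(fsr_rate, "fsr_rate", lower = 0, strict_lower = TRUE)
  check_number(imu_rate, "imu_rate", lower = 0, strict_lower = TRUE)
  check_number(cam_rate, "cam_rate", lower = 0, strict_lower = TRUE)
  if (fsr_rate != imu_rate) {
    abort("`fsr_rate` must equal `imu_rate`: the insole record carries FSR and IMU channels on one clock.",
          class = "gaitmos_config_error")
  }
  if (length(imu_noise_sd) != 2 || any(imu_noise_sd < 0)) {
    abort("`imu_noise_sd` must be two non-negative numbers c(accel, gyro).",
          class = "gaitmos_config_error")
  }
  check_number(cam_noise_sd, "cam_noise_sd", lower = 0)
  check_number(cam_dropout_prob, "cam_dropout_prob", lower = 0, upper = 1)
  check_number(leg_length, "leg_length", lower = 0, strict_lower = TRUE)
  check_number(clearance, "clearance", lower = 0)
  check_number(body_weight_load, "body_weight_load", lower = 0, strict_lower = TRUE)
  check_number(robot_distance, "robot_distance", lower = 0)
  check_number(seed, "seed")
  stopifnot(inherits(extrinsics, "rigid_transform"))
  structure(list(
    n_strides = as.integer(n_strides), nominal_sl = nominal_sl,
    nominal_st = nominal_st, nominal_sw = nominal_sw,
    nominal_swp = nominal_swp, cv_sl = cv_sl, cv_st = cv_st,
    fsr_rate = fsr_rate, imu_rate = imu_rate, cam_rate = cam_rate,
    imu_noise_sd = setNames(as.numeric(imu_noise_sd), c("accel", "gyro")),
    cam_noise_sd = cam_noise_sd, cam_dropout_prob = cam_dropout_prob,
    leg_length = leg_length, clearance = clearance,
    body_weight_load = body_weight_load, robot_distance = robot_distance,
    extrinsics = extrinsics, seed = as.integer(seed), g = 9.81
  ), class = "gait_sim_config")
}

# Minimum-jerk position profile and its first two derivatives on tau in [0,1].
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_d1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
minjerk_d2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

# C2 clearance bump, zero value/slope/curvature at both ends, peak 1 at 0.5.
clearance_bump <- function(tau) 64 * tau^3 * (1 - tau)^3
clearance_bump_d1 <- function(tau) 64 * (3 * tau^2 * (1 - tau)^3 - 3 * tau^3 * (1 - tau)^2)
clearance_bump_d2 <- function(tau) {
  64 * (6 * tau * (1 - tau)^3 - 18 * tau^2 * (1 - tau)^2 + 6 * tau^3 * (1 - tau))
}

# One foot's gait timeline as a segment table. h: n+1 heel-strike times,
# to: n toe-off times, px: n+1 placement x, lead_from: virtual placement x
# starting a lead-in swing at t = 0 (NA for the foot that starts in stance).
foot_segments <- function(h, to, px, y, t_end, lead_from = NA) {
  n <- length(to)
  segs <- list()
  if (!is.na(lead_from)) {
    segs[[length(segs) + 1L]] <- tibble::tibble(
      t0 = 0, t1 = h[1], type = "swing", x0 = lead_from, x1 = px[1])
  }
  for (k in seq_len(n)) {
    segs[[length(segs) + 1L]] <- tibble::tibble(
      t0 = h[k], t1 = to[k], type = "stance", x0 = px[k], x1 = px[k])
    segs[[length(segs) + 1L]] <- tibble::tibble(
      t0 = to[k], t1 = h[k + 1], type = "swing", x0 = px[k], x1 = px[k + 1])
  }
  segs[[length(segs) + 1L]] <- tibble::tibble(
    t0 = h[n + 1], t1 = t_end, type = "stance", x0 = px[n + 1], x1 = px[n + 1])
  out <- dplyr::bind_rows(segs)
  out$y <- y
  out
}

# Analytic foot kinematics (position, velocity, acceleration) at times t.
eval_foot <- function(t, segs, clearance) {
  idx <- findInterval(t, segs$t0)
  idx[idx < 1L] <- 1L
  s <- segs[idx, ]
  dur <- s$t1 - s$t0
  tau <- clamp((t - s$t0) / dur, 0, 1)
  swing <- s$type == "swing"
  dx <- s$x1 - s$x0
  x <- s$x0 + dx * minjerk(tau)
  vx <- ifelse(swing, dx * minjerk_d1(tau) / dur, 0)
  ax <- ifelse(swing, dx * minjerk_d2(tau) / dur^2, 0)
  z <- ifelse(swing, clearance * clearance_bump(tau), 0)
  vz <- ifelse(swing, clearance * clearance_bump_d1(tau) / dur, 0)
  az <- ifelse(swing, clearance * clearance_bump_d2(tau) / dur^2, 0)
  x[!swing] <- s$x0[!swing]
  tibble::tibble(t = t, x = x, y = s$y, z = z,
                 vx = vx, vy = 0, vz = vz, ax = ax, ay = 0, az = az,
                 stance = !swing, seg_u = tau)
}

# Double-bump insole load profile over normalised stance time u in [0,1]:
# heel and forefoot raised cosines on a weight-acceptance pedestal so that
# the total load steps sharply at heel strike and toe off.
stance_load_profile <- function(u) {
  heel <- ifelse(u <= 0.6, 0.5 * (1 - cos(2 * pi * u / 0.6)), 0)
  fore <- ifelse(u >= 0.4, 0.5 * (1 - cos(2 * pi * (u - 0.4) / 0.6)), 0)
  list(heel = heel, fore = fore, pedestal = rep(0.25, length(u)))
}

stride_times <- function(n, nominal, cv, offset = 0) {
  # strictly positive stride durations with the configured CV
  z <- rnorm(n)
  pmax(nominal * (1 + cv / 100 * z), 0.3 * nominal)
}

#' Generate a synthetic walking trial with ground truth
#'
#' Simulates straight-line overground walking: alternating stance and
#' minimum-jerk swing for each foot, a double-bump insole load profile that
#' is exactly zero during swing, IMU signals equal to the analytic second
#' derivative of the foot trajectory expressed in the sensor frame plus
#' gravity plus white noise, and camera fixes of the pelvis and both feet
#' subsampled at the camera rate with additive noise and Bernoulli dropout.
#' During ground-truth foot-flat (the whole stance phase here) the true
#' sensor acceleration magnitude equals g and the true angular rate is zero.
#'
#' The left foot strikes the ground exactly at `t = 0`; the right foot
#' starts mid lead-in swing and lands half a stride later, so the insole
#' streams contain exactly `n_strides` complete heel-strike-to-heel-strike
#' cycles per foot.
#'
#' @param config A [gait_sim_config()].
#' @return A `gait_trial` list with elements `config`, `truth` (events,
#'   strides, foot tracks, foot-flat intervals, centre-of-mass track),
#'   `insole_left`, `insole_right`, `camera`, and `robot_pose`, all tibbles.
#' @examples
#' trial <- simulate_walk(gait_sim_config(n_strides = 5, seed = 7))
#' trial$truth$strides
#' @export
simulate_walk <- function(config = gait_sim_config()) {
  if (!inherits(config, "gait_sim_config")) {
    abort("`config` must be created by gait_sim_config().",
          class = "gaitmos_config_error")
  }
  n <- config$n_strides
  swp <- config$nominal_swp / 100

  # -- ground-truth timing and placements (seed offset 0) --------------------
  set.seed(config$seed)
  st_l <- stride_times(n, config$nominal_st, config$cv_st)
  st_r <- stride_times(n, config$nominal_st, config$cv_st)
  sl_l <- pmax(config$nominal_sl * (1 + config$cv_sl / 100 * rnorm(n)), 0.1)
  sl_r <- pmax(config$nominal_sl * (1 + config$cv_sl / 100 * rnorm(n)), 0.1)

  h_l <- cumsum(c(0, st_l))
  h_r <- cumsum(c(config$nominal_st / 2, st_r))
  to_l <- h_l[1:n] + (1 - swp) * st_l
  to_r <- h_r[1:n] + (1 - swp) * st_r
  px_l <- cumsum(c(0, sl_l))
  px_r <- cumsum(c(config$nominal_sl / 2, sl_r))
  t_end <- max(h_l[n + 1], h_r[n + 1]) + 0.4

  segs_l <- foot_segments(h_l, to_l, px_l, +config$nominal_sw / 2, t_end)
  segs_r <- foot_segments(h_r, to_r, px_r, -config$nominal_sw / 2, t_end,
                          lead_from = px_r[1] - config$nominal_sl)

  # -- truth tables -----------------------------------------------------------
  events <- dplyr::bind_rows(
    tibble::tibble(foot = "left", kind = "HS", t = h_l),
    tibble::tibble(foot = "left", kind = "TO", t = to_l),
    tibble::tibble(foot = "right", kind = "HS", t = h_r),
    tibble::tibble(foot = "right", kind = "TO", t = to_r)) |>
    dplyr::arrange(.data$foot, .data$t)

  placements <- dplyr::bind_rows(
    tibble::tibble(foot = "left", k = 0:n, t_hs = h_l, x = px_l,
                   y = +config$nominal_sw / 2),
    tibble::tibble(foot = "right", k = 0:n, t_hs = h_r, x = px_r,
                   y = -config$nominal_sw / 2))

  truth_strides <- function(foot, h, to, px, y) {
    other <- placements[placements$foot != foot, ]
    sw <- vapply(seq_len(n), function(k) {
      prev <- other[other$t_hs < h[k], ]
      nxt <- other[other$t_hs > h[k], ]
      if (!nrow(prev) || !nrow(nxt)) return(NA_real_)
      a <- c(tail(prev$x, 1), tail(prev$y, 1))
      b <- c(nxt$x[1], nxt$y[1])
      point_line_distance(c(px[k], y), a, b)
    }, numeric(1))
    tibble::tibble(
      foot = foot, stride = seq_len(n), t_hs = h[1:n], t_to = to,
      t_next_hs = h[2:(n + 1)], st = diff(h), swing = h[2:(n + 1)] - to,
      swp = 100 * (h[2:(n + 1)] - to) / diff(h),
      sl = diff(px), sv = diff(px) / diff(h), sw = sw)
  }
  strides <- dplyr::bind_rows(
    truth_strides("left", h_l, to_l, px_l, +config$nominal_sw / 2),
    truth_strides("right", h_r, to_r, px_r, -config$nominal_sw / 2))

  ff <- dplyr::bind_rows(
    tibble::tibble(foot = "left", t_start = c(h_l[1:n], h_l[n + 1]),
                   t_end = c(to_l, t_end)),
    tibble::tibble(foot = "right", t_start = c(h_r[1:n], h_r[n + 1]),
                   t_end = c(to_r, t_end)))

  # -- insole streams ---------------------------------------------------------
  t_imu <- seq(0, t_end, by = 1 / config$imu_rate)
  traj_l <- eval_foot(t_imu, segs_l, config$clearance)
  traj_r <- eval_foot(t_imu, segs_r, config$clearance)

  make_insole <- function(traj, foot, noise_seed) {
    p <- stance_load_profile(traj$seg_u)
    on <- as.numeric(traj$stance)
    w <- config$body_weight_load
    fsr <- cbind(
      fsr1 = on * w * (p$pedestal / 8 + 0.375 * p$heel),
      fsr2 = on * w * (p$pedestal / 8 + 0.375 * p$heel),
      fsr3 = on * w * (p$pedestal / 8 + 0.125 * p$fore),
      fsr4 = on * w * (p$pedestal / 8 + 0.125 * p$fore),
      fsr5 = on * w * (p$pedestal / 8 + 0.125 * p$fore),
      fsr6 = on * w * (p$pedestal / 8 + 0.125 * p$fore),
      fsr7 = on * w * (p$pedestal / 8 + 0.125 * p$fore),
      fsr8 = on * w * (p$pedestal / 8 + 0.125 * p$fore))
    set.seed(config$seed + noise_seed)
    m <- length(traj$t)
    acc_sd <- config$imu_noise_sd[["accel"]]
    gyr_sd <- config$imu_noise_sd[["gyro"]]
    # sensor orientation is identity, so the specific force in the sensor
    # frame is the world acceleration plus gravity along +z
    tibble::tibble(
      t = traj$t, foot = foot,
      ax = traj$ax + rnorm(m, 0, acc_sd),
      ay = traj$ay + rnorm(m, 0, acc_sd),
      az = traj$az + config$g + rnorm(m, 0, acc_sd),
      gx = rnorm(m, 0, gyr_sd), gy = rnorm(m, 0, gyr_sd),
      gz = rnorm(m, 0, gyr_sd)) |>
      dplyr::bind_cols(tibble::as_tibble(fsr)) |>
      dplyr::relocate(dplyr::starts_with("fsr"), .after = "foot")
  }
  insole_left <- make_insole(traj_l, "left", 1L)
  insole_right <- make_insole(traj_r, "right", 2L)

  # -- pelvis / CoM truth -----------------------------------------------------
  # midpoint of the feet plus a small mediolateral sway at stride frequency
  # (the CoM leans towards the stance foot each step)
  sway_a <- 0.25 * config$nominal_sw
  sway_w <- 2 * pi / config$nominal_st
  com <- tibble::tibble(
    t = t_imu,
    x = (traj_l$x + traj_r$x) / 2,
    y = (traj_l$y + traj_r$y) / 2 + sway_a * sin(sway_w * t_imu),
    z = config$leg_length,
    vx = (traj_l$vx + traj_r$vx) / 2,
    vy = (traj_l$vy + traj_r$vy) / 2 + sway_a * sway_w * cos(sway_w * t_imu))

  # -- robot pose track (leads the pelvis at constant speed) ------------------
  v_avg <- (com$x[nrow(com)] - com$x[1]) / t_end
  robot_x <- function(t) com$x[1] + v_avg * t + config$robot_distance

  set.seed(config$seed + 3L)
  n_cam <- floor(t_end * config$cam_rate) + 1L
  t_cam <- (seq_len(n_cam) - 1L) / config$cam_rate +
    runif(n_cam, 0, 0.4 / config$cam_rate)
  t_cam <- t_cam[t_cam <= t_end]

  robot_pose <- tibble::tibble(t = t_cam, x = robot_x(t_cam), y = 0, theta = 0)

  cam_l <- eval_foot(t_cam, segs_l, config$clearance)
  cam_r <- eval_foot(t_cam, segs_r, config$clearance)
  com_cam <- tibble::tibble(
    x = (cam_l$x + cam_r$x) / 2,
    y = (cam_l$y + cam_r$y) / 2 + sway_a * sin(sway_w * t_cam),
    z = config$leg_length)

  world_to_sensor <- function(pts, pose) {
    # world -> robot -> camera
    cam_in_world <- lapply(seq_len(nrow(pose)), function(i) {
      tf <- invert_rigid(robot_pose_transform(pose$x[i], pose$y[i],
                                              pose$theta[i]))
      apply_rigid(invert_rigid(config$extrinsics),
                  apply_rigid(tf, pts[i, , drop = FALSE]))
    })
    do.call(rbind, cam_in_world)
  }

  make_fixes <- function(pts, target) {
    sens <- world_to_sensor(as.matrix(pts[, c("x", "y", "z")]), robot_pose)
    m <- nrow(sens)
    tibble::tibble(
      t = t_cam, target = target,
      x = sens[, 1] + rnorm(m, 0, config$cam_noise_sd),
      y = sens[, 2] + rnorm(m, 0, config$cam_noise_sd),
      z = sens[, 3] + rnorm(m, 0, config$cam_noise_sd),
      qw = 1, qx = 0, qy = 0, qz = 0,
      valid = runif(m) >= config$cam_dropout_prob)
  }
  camera <- dplyr::bind_rows(
    make_fixes(com_cam, "pelvis"),
    make_fixes(cam_l, "left_foot"),
    make_fixes(cam_r, "right_foot")) |>
    dplyr::arrange(.data$t, .data$target)

  structure(list(
    config = config,
    truth = list(events = events, strides = strides, placements = placements,
                 ff = ff, foot_left = traj_l, foot_right = traj_r, com = com),
    insole_left = insole_left, insole_right = insole_right,
    camera = camera, robot_pose = robot_pose), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial>", x$config$n_strides, "strides/foot,",
      sprintf("%.1f s,", max(x$insole_left$t)),
      nrow(x$insole_left), "insole samples/foot,",
      sum(x$camera$valid), "valid camera fixes\n")
  invisible(x)
}

# perpendicular distance from point p to the infinite line through a and b
point_line_distance <- function(p, a, b) {
  d <- b - a
  abs(d[1] * (p[2] - a[2]) - d[2] * (p[1] - a[1])) / sqrt(sum(d^2))
}
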