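#' Configuration for the foot-pose extended Kalman filter
#'
#' The filter fuses strapdown IMU prediction with camera position fixes and
#' zero-velocity pseudo-measurements (ZUPT) applied during detected
#' foot-flat. The error state is 9-dimensional (position, velocity,
#' orientation error); the unit quaternion is held outside the covariance.
#'
#' @param accel_noise_sd,gyro_noise_sd Process noise SD of the accelerometer
#'   (m/s^2) and gyroscope (rad/s), referenced to the IMU sample rate.
#' @param cam_pos_noise_sd Camera position measurement noise SD (m).
#' @param zupt_noise_sd Zero-velocity pseudo-measurement noise SD (m/s).
#' @param ff_accel_tol Foot-flat gate on the normalised acceleration:
#'   foot-flat requires `| ||accel|| / g - 1 | < ff_accel_tol`
#'   (dimensionless).
#' @param ff_gyro_tol Additional gyroscope magnitude gate (rad/s).
#' @param ff_min_dwell Minimum duration (s) of a reported foot-flat interval.
#' @param g Gravitational acceleration (m/s^2).
#' @param p0_sd,v0_sd,th0_sd Initial state uncertainty (m, m/s, rad).
#' @return An `ekf_config` list.
#' @export
ekf_config <- function(accel_noise_sd = 0.05,
                       gyro_noise_sd = 0.01,
                       cam_pos_noise_sd = 0.01,
                       zupt_noise_sd = 0.01,
                       ff_accel_tol = 0.05,
                       ff_gyro_tol = 0.5,
                       ff_min_dwell = 0.1,
                       g = 9.81,
                       p0_sd = 0.2, v0_sd = 0.2, th0_sd = 0.05) {
  for (nm in c("accel_noise_sd", "gyro_noise_sd", "cam_pos_noise_sd",
               "zupt_noise_sd")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_number(ff_accel_tol, "ff_accel_tol", lower = 0, strict_lower = TRUE)
  check_number(ff_gyro_tol, "ff_gyro_tol", lower = 0, strict_lower = TRUE)
  check_number(ff_min_dwell, "ff_min_dwell", lower = 0)
  check_number(g, "g", lower = 0, strict_lower = TRUE)
  structure(list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 cam_pos_noise_sd = cam_pos_noise_sd,
                 zupt_noise_sd = zupt_noise_sd, ff_accel_tol = ff_accel_tol,
                 ff_gyro_tol = ff_gyro_tol, ff_min_dwell = ff_min_dwell,
                 g = g, p0_sd = p0_sd, v0_sd = v0_sd, th0_sd = th0_sd),
            class = "ekf_config")
}

#' Detect foot-flat intervals from IMU channels
#'
#' Foot-flat is the mid-stance phase during which the foot is stationary, so
#' the accelerometer reads pure gravity and the gyroscope reads zero.
#' Returns the maximal intervals of duration at least `ff_min_dwell` on
#' which `| ||accel||/g - 1 | < ff_accel_tol` and `||gyro|| < ff_gyro_tol`.
#'
#' @param insole Insole stream with columns `t`, `ax`..`az`, `gx`..`gz` (and
#'   optionally `foot`).
#' @param config An [ekf_config()].
#' @return Tibble with columns `foot`, `t_start`, `t_end`.
#' @export
detect_foot_flat <- function(insole, config = ekf_config()) {
  if (nrow(insole) == 0) {
    return(tibble::tibble(foot = character(), t_start = numeric(),
                          t_end = numeric()))
  }
  check_columns(insole, c("t", "ax", "ay", "az", "gx", "gy", "gz"), "insole")
  check_time_sorted(insole$t, "insole")
  foot <- if ("foot" %in% names(insole)) insole$foot[1] else NA_character_
  anorm <- sqrt(insole$ax^2 + insole$ay^2 + insole$az^2)
  gnorm <- sqrt(insole$gx^2 + insole$gy^2 + insole$gz^2)
  flat <- abs(anorm / config$g - 1) < config$ff_accel_tol &
    gnorm < config$ff_gyro_tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- tibble::tibble(
    foot = foot,
    t_start = insole$t[starts[r$values]],
    t_end = insole$t[ends[r$values]])
  iv[iv$t_end - iv$t_start >= config$ff_min_dwell, ]
}

#' Create an EKF state
#'
#' @param p,v Position (m) and velocity (m/s), world frame, length 3.
#' @param q Unit quaternion (w, x, y, z), sensor to world.
#' @param P 9x9 covariance over the error state (position, velocity,
#'   orientation error).
#' @param t Timestamp (s).
#' @return An `ekf_state` list.
#' @export
ekf_state <- function(p = c(0, 0, 0), v = c(0, 0, 0), q = c(1, 0, 0, 0),
                      P = diag(c(rep(0.2^2, 3), rep(0.2^2, 3), rep(0.05^2, 3))),
                      t = 0) {
  stopifnot(length(p) == 3, length(v) == 3, length(q) == 4,
            all(dim(P) == c(9, 9)))
  structure(list(p = as.numeric(p), v = as.numeric(v),
                 q = quat_normalize(as.numeric(q)), P = (P + t(P)) / 2, t = t),
            class = "ekf_state")
}

#' EKF strapdown prediction step
#'
#' Advances orientation by the gyro rotation over `dt`, velocity by the
#' world-frame specific force minus gravity, and position by the velocity
#' (trapezoid-free, with the 0.5 a dt^2 term); propagates the covariance
#' through the linearised error-state transition.
#'
#' @param state An [ekf_state()].
#' @param accel,gyro IMU specific force (m/s^2) and angular rate (rad/s),
#'   sensor frame, length 3.
#' @param dt Time step (s), > 0.
#' @param config An [ekf_config()].
#' @return The predicted `ekf_state`.
#' @export
ekf_predict <- function(state, accel, gyro, dt, config = ekf_config()) {
  if (!is.finite(dt) || dt <= 0 || !all(is.finite(accel)) ||
      !all(is.finite(gyro))) {
    abort("non-finite IMU input or non-positive dt in ekf_predict().",
          class = "gaitmos_numeric_error")
  }
  R <- quat_to_matrix(state$q)
  a_world <- as.numeric(R %*% accel) - c(0, 0, config$g)
  p <- state$p + state$v * dt + 0.5 * a_world * dt^2
  v <- state$v + a_world * dt
  q <- quat_normalize(quat_multiply(state$q, quat_from_rotvec(gyro * dt)))

  F <- diag(9)
  F[1:3, 4:6] <- diag(3) * dt
  F[4:6, 7:9] <- -R %*% skew(accel) * dt
  F[7:9, 7:9] <- t(quat_to_matrix(quat_from_rotvec(gyro * dt)))
  Q <- diag(c(rep(1e-12, 3),
              rep((config$accel_noise_sd * dt)^2, 3),
              rep((config$gyro_noise_sd * dt)^2, 3)))
  P <- F %*% state$P %*% t(F) + Q
  ekf_state(p, v, q, P, state$t + dt)
}

# shared linear measurement update over the 9-dim error state
ekf_linear_update <- function(state, H, z, R_meas) {
  P <- state$P
  S <- H %*% P %*% t(H) + R_meas
  K <- P %*% t(H) %*% solve(S)
  innov <- z
  dx <- as.numeric(K %*% innov)
  IKH <- diag(9) - K %*% H
  P_new <- IKH %*% P %*% t(IKH) + K %*% R_meas %*% t(K) # Joseph form
  p <- state$p + dx[1:3]
  v <- state$v + dx[4:6]
  q <- quat_normalize(quat_multiply(quat_from_rotvec(dx[7:9]), state$q))
  ekf_state(p, v, q, P_new, state$t)
}

#' EKF camera position update
#'
#' Transforms a camera-frame fix into the world frame through the robot pose
#' and the camera extrinsics, then applies a standard EKF position update.
#' Invalid fixes are skipped (state returned unchanged).
#'
#' @param state An [ekf_state()].
#' @param fix One camera fix: list/row with `x`, `y`, `z` (camera frame) and
#'   `valid`.
#' @param robot_pose Robot pose at fix time: list/row with `x`, `y`, `theta`.
#' @param extrinsics [rigid_transform()] camera -> robot.
#' @param config An [ekf_config()].
#' @return The updated `ekf_state`.
#' @export
ekf_update_camera <- function(state, fix, robot_pose,
                              extrinsics = rigid_transform(),
                              config = ekf_config()) {
  if (!isTRUE(as.logical(fix$valid))) {
    inform("camera fix flagged invalid; update skipped.",
           class = "gaitmos_skip")
    return(state)
  }
  world <- sensor_to_world(c(fix$x, fix$y, fix$z),
                           robot_pose = robot_pose, extrinsics = extrinsics)
  H <- cbind(diag(3), matrix(0, 3, 6))
  z <- as.numeric(world) - state$p
  ekf_linear_update(state, H, z, diag(3) * config$cam_pos_noise_sd^2)
}

#' EKF zero-velocity update
#'
#' Applies the pseudo-measurement v = 0 with noise `zupt_noise_sd`; called
#' during detected foot-flat intervals when the foot is known stationary.
#'
#' @inheritParams ekf_update_camera
#' @return The updated `ekf_state`.
#' @export
ekf_update_zupt <- function(state, config = ekf_config()) {
  H <- cbind(matrix(0, 3, 3), diag(3), matrix(0, 3, 3))
  z <- -state$v
  ekf_linear_update(state, H, z, diag(3) * config$zupt_noise_sd^2)
}

#' Run the foot-pose EKF over one foot's streams
#'
#' Applies the strapdown prediction at the IMU rate, a camera position
#' update at each valid fix (attached to the nearest IMU step), and
#' zero-velocity updates at every step inside a detected foot-flat interval.
#' With an empty camera stream the filter degrades to IMU + ZUPT dead
#' reckoning (a warning is raised, since absolute position then drifts).
#'
#' @param insole One foot's insole stream (columns `t`, `ax`..`gz`,
#'   `fsr1`..`fsr8` optional).
#' @param camera Camera stream for this foot: columns `t`, `x`, `y`, `z`,
#'   `valid` (camera frame). May have zero rows.
#' @param robot_pose Robot pose track: columns `t`, `x`, `y`, `theta`.
#' @param config An [ekf_config()].
#' @param extrinsics [rigid_transform()] camera -> robot.
#' @param ff Optional foot-flat intervals (tibble `t_start`, `t_end`);
#'   computed with [detect_foot_flat()] when `NULL`.
#' @return A `foot_trajectory` tibble: `t`, `x`, `y`, `z`, `vx`, `vy`, `vz`,
#'   `qw`, `qx`, `qy`, `qz`, `trace_P`.
#' @export
run_ekf <- function(insole, camera, robot_pose, config = ekf_config(),
                    extrinsics = rigid_transform(), ff = NULL) {
  check_columns(insole, c("t", "ax", "ay", "az", "gx", "gy", "gz"), "insole")
  if (nrow(insole) < 2) {
    abort("insole stream too short for filtering.", class = "gaitmos_input_error")
  }
  check_time_sorted(insole$t, "insole")
  has_cam <- !is.null(camera) && nrow(camera) > 0
  if (has_cam) {
    check_columns(camera, c("t", "x", "y", "z", "valid"), "camera")
    if (max(camera$t) < min(insole$t) || min(camera$t) > max(insole$t)) {
      abort("camera and insole streams do not overlap in time.",
            class = "gaitmos_input_error")
    }
  } else {
    warn("camera stream empty: running IMU + ZUPT only; absolute position will drift.")
  }
  if (is.null(ff)) ff <- detect_foot_flat(insole, config)

  nt <- nrow(insole)
  # camera fixes grouped by the IMU interval (t[i-1], t[i]] they fall in;
  # each fix is applied at its exact timestamp by splitting the predict step
  cam_at <- vector("list", nt)
  cam <- NULL
  if (has_cam) {
    cam <- camera[camera$valid & camera$t >= insole$t[1] &
                    camera$t <= insole$t[nt], , drop = FALSE]
    if (nrow(cam)) {
      idx <- findInterval(cam$t, insole$t, left.open = TRUE) + 1L
      idx <- clamp(idx, 1L, nt)
      for (j in seq_along(idx)) {
        cam_at[[idx[j]]] <- c(cam_at[[idx[j]]], list(cam[j, ]))
      }
    }
  }
  in_ff <- rep(FALSE, nt)
  if (nrow(ff)) {
    for (j in seq_len(nrow(ff))) {
      in_ff <- in_ff | (insole$t >= ff$t_start[j] & insole$t <= ff$t_end[j])
    }
  }
  pose_at <- function(tc) {
    list(x = approx(robot_pose$t, robot_pose$x, tc, rule = 2)$y,
         y = approx(robot_pose$t, robot_pose$y, tc, rule = 2)$y,
         theta = approx(robot_pose$t, robot_pose$theta, tc, rule = 2)$y)
  }

  # initialise at the first valid camera fix if available
  p0 <- c(0, 0, 0)
  if (has_cam && !is.null(cam) && nrow(cam)) {
    f1 <- cam[1, ]
    p0 <- as.numeric(sensor_to_world(c(f1$x, f1$y, f1$z),
                                     robot_pose = pose_at(f1$t),
                                     extrinsics = extrinsics))
  }
  st <- ekf_state(p = p0, v = c(0, 0, 0), q = quat_identity(),
                  P = diag(c(rep(config$p0_sd^2, 3), rep(config$v0_sd^2, 3),
                             rep(config$th0_sd^2, 3))),
                  t = insole$t[1])

  out <- matrix(NA_real_, nt, 12)
  record <- function(i, s) {
    out[i, ] <<- c(s$t, s$p, s$v, s$q, sum(diag(s$P)))
  }
  for (fx in cam_at[[1]] %||% list()) {
    st <- ekf_update_camera(st, fx, pose_at(fx$t), extrinsics, config)
  }
  if (in_ff[1]) st <- ekf_update_zupt(st, config)
  record(1L, st)
  for (i in 2:nt) {
    # trapezoidal strapdown: average the IMU readings bracketing the interval
    imu_a <- c(insole$ax[i] + insole$ax[i - 1],
               insole$ay[i] + insole$ay[i - 1],
               insole$az[i] + insole$az[i - 1]) / 2
    imu_g <- c(insole$gx[i] + insole$gx[i - 1],
               insole$gy[i] + insole$gy[i - 1],
               insole$gz[i] + insole$gz[i - 1]) / 2
    # predict across the interval, pausing at each camera fix time
    for (fx in cam_at[[i]] %||% list()) {
      dt_sub <- fx$t - st$t
      if (dt_sub > 1e-9) st <- ekf_predict(st, imu_a, imu_g, dt_sub, config)
      st <- ekf_update_camera(st, fx, pose_at(fx$t), extrinsics, config)
    }
    dt_sub <- insole$t[i] - st$t
    if (dt_sub > 1e-9) st <- ekf_predict(st, imu_a, imu_g, dt_sub, config)
    st$t <- insole$t[i]
    if (in_ff[i]) st <- ekf_update_zupt(st, config)
    record(i, st)
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("t", "x", "y", "z", "vx", "vy", "vz",
                   "qw", "qx", "qy", "qz", "trace_P")
  if ("foot" %in% names(insole)) traj$foot <- insole$foot[1]
  class(traj) <- c("foot_trajectory", class(traj))
  traj
}

# trajectory state nearest to time tq
traj_at <- function(traj, tq) {
  i <- which.min(abs(traj$t - tq))
  traj[i, ]
}

#' Fill spatial gait parameters from fused foot trajectories
#'
#' Stride length (SL) is the horizontal distance between the estimated foot
#' positions at the midpoints of consecutive same-foot foot-flat intervals;
#' stride velocity SV = SL / ST; step width (SW) is the lateral distance
#' from a foot's foot-flat position to the line through the two flanking
#' contralateral foot-flat positions. Strides without flanking foot-flats
#' are excluded (flag `spatial_ok = FALSE`).
#'
#' @param strides Stride table from [temporal_parameters()] (both feet).
#' @param traj_left,traj_right Fused trajectories from [run_ekf()].
#' @param ff_left,ff_right Foot-flat intervals from [detect_foot_flat()].
#' @return `strides` with `sl`, `sv`, `sw` filled and a logical
#'   `spatial_ok` column.
#' @export
spatial_parameters <- function(strides, traj_left, traj_right,
                               ff_left, ff_right) {
  anchors <- function(traj, ff) {
    if (!nrow(ff)) {
      return(tibble::tibble(t_mid = numeric(), x = numeric(), y = numeric()))
    }
    mid <- (ff$t_start + ff$t_end) / 2
    pos <- purrr::map(mid, ~traj_at(traj, .x))
    tibble::tibble(t_mid = mid,
                   x = purrr::map_dbl(pos, "x"),
                   y = purrr::map_dbl(pos, "y"))
  }
  anc <- list(left = anchors(traj_left, ff_left),
              right = anchors(traj_right, ff_right))

  fill_one <- function(row) {
    own <- anc[[row$foot]]
    other <- anc[[setdiff(c("left", "right"), row$foot)]]
    # anchor of the stance starting the stride and of the next stance
    a0 <- own[own$t_mid >= row$t_hs & own$t_mid <= row$t_to, ]
    a1 <- own[own$t_mid >= row$t_next_hs, ]
    if (nrow(a0) != 1 || nrow(a1) < 1) {
      row$spatial_ok <- FALSE
      inform(sprintf("stride at t_hs=%.2f s (%s) lacks flanking foot-flat; excluded.",
                     row$t_hs, row$foot), class = "gaitmos_skip")
      return(row)
    }
    a1 <- a1[1, ]
    row$sl <- sqrt((a1$x - a0$x)^2 + (a1$y - a0$y)^2)
    row$sv <- row$sl / row$st
    q_prev <- other[other$t_mid < a0$t_mid, ]
    q_next <- other[other$t_mid > a0$t_mid, ]
    if (nrow(q_prev) && nrow(q_next)) {
      row$sw <- point_line_distance(
        c(a0$x, a0$y),
        c(tail(q_prev$x, 1), tail(q_prev$y, 1)),
        c(q_next$x[1], q_next$y[1]))
    }
    row$spatial_ok <- TRUE
    row
  }
  strides$spatial_ok <- NA
  strides |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(fill_one) |>
    dplyr::bind_rows()
}
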