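#' Guidance controller configuration
#'
#' Parameters of the robot's distance-keeping control loop. The robot leads
#' the walker and regulates the measured human-robot distance to `d_r` with
#' a PI law on the distance error `e = d_r - d_meas`:
#' `v_PI = clamp(kp * e + ki * integral(e), 0, v_max)`, so the robot slows
#' (and ultimately stops) when the walker lags and speeds up when the walker
#' closes in. The integral term removes the steady-state offset and is
#' clamped to `integral_limit` (anti-windup).
#'
#' @param d_r Desired human-robot distance (m).
#' @param kp Proportional gain (1/s).
#' @param ki Integral gain (1/s^2).
#' @param v_max,omega_max Velocity limits (m/s, rad/s).
#' @param dt Control period (s).
#' @param integral_limit Anti-windup bound on the error integral (m s);
#'   defaults to `v_max / ki`.
#' @param transient_head,transient_tail Seconds excluded at the start/end of
#'   a run by [error_metrics()].
#' @param lookahead Pure-pursuit lookahead distance (m).
#' @param v_nominal Planner nominal speed (m/s) used to shape the path-
#'   tracking command before distance scaling.
#' @param fov_apex Depth-camera field-of-view apex angle (deg).
#' @param fov_near,fov_far Near/far clipping distances (m).
#' @param meas_noise_sd SD of the distance measurement noise (m).
#' @return A `guidance_config` list.
#' @export
guidance_config <- function(d_r = 1.5, kp = 1.0, ki = 0.2,
                            v_max = 1.2, omega_max = 1.5, dt = 0.05,
                            integral_limit = NULL,
                            transient_head = 15, transient_tail = 5,
                            lookahead = 0.6, v_nominal = 1.0,
                            fov_apex = 120, fov_near = 0.5, fov_far = 3.86,
                            meas_noise_sd = 0) {
  check_number(d_r, "d_r", lower = 0, strict_lower = TRUE)
  check_number(kp, "kp", lower = 0)
  check_number(ki, "ki", lower = 0)
  check_number(v_max, "v_max", lower = 0, strict_lower = TRUE)
  check_number(omega_max, "omega_max", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(meas_noise_sd, "meas_noise_sd", lower = 0)
  if (is.null(integral_limit)) {
    integral_limit <- if (ki > 0) v_max / ki else Inf
  }
  structure(list(d_r = d_r, kp = kp, ki = ki, v_max = v_max,
                 omega_max = omega_max, dt = dt,
                 integral_limit = integral_limit,
                 transient_head = transient_head,
                 transient_tail = transient_tail, lookahead = lookahead,
                 v_nominal = v_nominal, fov_apex = fov_apex,
                 fov_near = fov_near, fov_far = fov_far,
                 meas_noise_sd = meas_noise_sd), class = "guidance_config")
}

#' Closed oval walking track
#'
#' Two straights joined by two semicircular end caps, parameterised by arc
#' length (counter-clockwise). The defaults (13 m straights, 1.91 m end
#' radius) give a human path of 2*13 + 2*pi*1.91 = 38.0 m, the length of
#' the community-centre track. The robot path is an inward offset of the
#' human path (`offset = 0` makes them identical, which also centres the
#' following walker on the rear camera axis).
#'
#' @param straight Straight-section length (m).
#' @param radius End-cap radius of the human path (m).
#' @param offset Inward offset of the robot path (m), < `radius`.
#' @return A `walk_path` list with fields `length` and `point(s)`; `point`
#'   maps arc length (vectorised, wrapped modulo `length`) to a tibble
#'   `x`, `y`, `theta` (tangent heading), `curvature`.
#' @export
oval_path <- function(straight = 13, radius = 1.91, offset = 0) {
  check_number(straight, "straight", lower = 0)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(offset, "offset", lower = 0)
  if (offset >= radius) {
    abort("`offset` must be smaller than the end-cap radius.",
          class = "gaitmos_config_error")
  }
  r <- radius - offset
  L1 <- straight          # bottom straight, y = -r, +x direction
  L2 <- pi * r            # right cap
  len <- 2 * straight + 2 * pi * r
  point <- function(s) {
    s <- s %% len
    x <- y <- th <- kap <- numeric(length(s))
    seg1 <- s < L1
    x[seg1] <- s[seg1]; y[seg1] <- -r; th[seg1] <- 0; kap[seg1] <- 0
    seg2 <- s >= L1 & s < L1 + L2
    a <- (s[seg2] - L1) / r - pi / 2
    x[seg2] <- straight + r * cos(a); y[seg2] <- r * sin(a)
    th[seg2] <- a + pi / 2; kap[seg2] <- 1 / r
    seg3 <- s >= L1 + L2 & s < 2 * L1 + L2
    x[seg3] <- straight - (s[seg3] - L1 - L2); y[seg3] <- r
    th[seg3] <- pi; kap[seg3] <- 0
    seg4 <- s >= 2 * L1 + L2
    a <- (s[seg4] - 2 * L1 - L2) / r + pi / 2
    x[seg4] <- r * cos(a); y[seg4] <- r * sin(a)
    th[seg4] <- a + pi / 2; kap[seg4] <- 1 / r
    tibble::tibble(s = s, x = x, y = y, theta = wrap_angle(th),
                   curvature = kap)
  }
  structure(list(straight = straight, radius = r, length = len,
                 point = point), class = "walk_path")
}

#' Straight-line path
#'
#' Open straight track along +x, useful for isolating the distance
#' controller from path curvature.
#'
#' @param length Track length (m); arc lengths are clamped, not wrapped.
#' @return A `walk_path` list (see [oval_path()]).
#' @export
straight_path <- function(length = 1e4) {
  point <- function(s) {
    s <- clamp(s, 0, length)
    tibble::tibble(s = s, x = s, y = 0, theta = 0, curvature = 0)
  }
  structure(list(straight = length, radius = Inf, length = length,
                 point = point), class = "walk_path")
}

#' Build matched human and robot paths
#'
#' @param straight,radius Oval geometry of the human path (m); defaults give
#'   the 38 m track.
#' @param offset Inward offset of the robot path (m).
#' @return List with elements `human` and `robot`, both `walk_path`s.
#' @export
build_paths <- function(straight = 13, radius = 1.91, offset = 0) {
  list(human = oval_path(straight, radius, 0),
       robot = oval_path(straight, radius, offset))
}

#' Exact unicycle kinematic step
#'
#' Advances a differential-drive robot state by one step of constant
#' commands `(v, omega)`: a straight segment when `omega = 0`, otherwise an
#' exact circular arc of radius `v / omega`. The heading is wrapped to
#' (-pi, pi].
#'
#' @param q Robot state: list/row with `x`, `y`, `theta` (and optionally
#'   `t`).
#' @param u Control input: list with `v` (m/s) and `omega` (rad/s).
#' @param dt Step duration (s), > 0.
#' @return Updated state list `x`, `y`, `theta`, `t`.
#' @export
step_kinematics <- function(q, u, dt) {
  vals <- c(q$x, q$y, q$theta, u$v, u$omega, dt)
  if (!all(is.finite(vals)) || dt <= 0) {
    abort("non-finite state/input or non-positive dt in step_kinematics().",
          class = "gaitmos_numeric_error")
  }
  if (abs(u$omega) < 1e-12) {
    x <- q$x + u$v * cos(q$theta) * dt
    y <- q$y + u$v * sin(q$theta) * dt
    th <- q$theta
  } else {
    rr <- u$v / u$omega
    th1 <- q$theta + u$omega * dt
    x <- q$x + rr * (sin(th1) - sin(q$theta))
    y <- q$y - rr * (cos(th1) - cos(q$theta))
    th <- th1
  }
  list(x = x, y = y, theta = wrap_angle(th), t = (q$t %||% 0) + dt)
}

#' PI distance-keeping control
#'
#' Computes the speed command from the measured human-robot distance.
#' With the robot leading, the error is `e = d_r - d_meas`:
#' `v_PI = clamp(kp * e + ki * integral(e), 0, v_max)`. The robot slows
#' (clamping at zero) when the walker lags behind the desired distance and
#' speeds up when the walker closes in; the clamped integral removes the
#' steady-state error without windup.
#'
#' @param d_meas Measured distance (m), >= 0.
#' @param config A [guidance_config()].
#' @param state PI state list with `integral` (m s); `pi_state_init()`
#'   creates one.
#' @param dt Time since the last update (s).
#' @return List with `v_pi` (m/s) and the updated `state`.
#' @export
pi_distance_control <- function(d_meas, config, state = pi_state_init(),
                                dt = config$dt) {
  check_number(d_meas, "d_meas", lower = 0)
  e <- config$d_r - d_meas
  integral <- clamp(state$integral + e * dt,
                    -config$integral_limit, config$integral_limit)
  v <- clamp(config$kp * e + config$ki * integral, 0, config$v_max)
  list(v_pi = v, state = list(integral = integral, last_e = e))
}

#' @rdname pi_distance_control
#' @export
pi_state_init <- function() list(integral = 0, last_e = 0)

#' Curvature-preserving control scaling
#'
#' Replaces the planner's linear velocity with the PI speed while keeping
#' the commanded curvature `omega / v` unchanged, so the tracked path is
#' preserved: `(v_pi, omega * v_pi / v)`. When the planned speed is (near)
#' zero the curvature is undefined and `(v_pi, 0)` is returned with a
#' notification.
#'
#' @param u_plan Planned control: list with `v`, `omega`.
#' @param v_pi Speed from [pi_distance_control()] (m/s).
#' @param eps Planned-speed magnitude below which curvature is undefined.
#' @return Scaled control list `v`, `omega`.
#' @export
scale_control <- function(u_plan, v_pi, eps = 1e-9) {
  if (abs(u_plan$v) < eps) {
    inform("planned speed ~ 0: curvature undefined, omega set to 0.",
           class = "gaitmos_skip")
    return(list(v = v_pi, omega = 0))
  }
  list(v = v_pi, omega = u_plan$omega * v_pi / u_plan$v)
}

#' Pure-pursuit path tracking command
#'
#' Steers towards the point `lookahead` metres ahead of the robot's current
#' arc-length station on the path, at the nominal planner speed. Stands in
#' for a full local motion planner; the distance-keeping law and the
#' curvature-preserving scaling operate on its output.
#'
#' @param q Robot state (`x`, `y`, `theta`).
#' @param path A `walk_path`.
#' @param s Current arc-length station of the robot on `path`.
#' @param config A [guidance_config()].
#' @return List `u` (`v`, `omega`) and the updated station `s`.
#' @export
path_tracker <- function(q, path, s, config = guidance_config()) {
  # refine the station by local projection (the robot moves continuously)
  cand <- s + seq(-0.25, 1, by = 0.01) * max(config$v_max * config$dt * 20, 0.5)
  pts <- path$point(cand)
  i <- which.min((pts$x - q$x)^2 + (pts$y - q$y)^2)
  s <- cand[i]
  target <- path$point(s + config$lookahead)
  dx <- target$x - q$x; dy <- target$y - q$y
  ld <- sqrt(dx^2 + dy^2)
  alpha <- wrap_angle(atan2(dy, dx) - q$theta)
  curv <- if (ld < 1e-9) 0 else 2 * sin(alpha) / ld
  v <- config$v_nominal
  omega <- clamp(v * curv, -config$omega_max, config$omega_max)
  list(u = list(v = v, omega = omega), s = s)
}

#' Simulate a robot-guided walk
#'
#' Closed-loop simulation of the guided-walking control loop: the human
#' advances along the human path at `human_speed` (a constant or a function
#' of time), the robot leads on the robot path, measures the Euclidean
#' ground-plane distance to the human (optionally with Gaussian noise),
#' runs the PI distance law, scales the pure-pursuit command to preserve
#' curvature, and steps the exact unicycle kinematics. Also records whether
#' the human lies inside the rear depth-camera field of view (a truncated
#' cone with the configured apex angle and clipping planes).
#'
#' @param paths List with `human` and `robot` `walk_path`s (see
#'   [build_paths()]); a single `walk_path` is used for both.
#' @param human_speed Constant speed (m/s) or function of time `f(t)`.
#' @param config A [guidance_config()].
#' @param duration Simulated time (s).
#' @param seed Seed for the measurement noise.
#' @return A `guided_walk` object: list with `series` (per-step tibble),
#'   `config`, and `diverged` flag (persistent `d > 2 d_r`).
#' @export
simulate_guided_walk <- function(paths, human_speed = 1.0,
                                 config = guidance_config(),
                                 duration = 120, seed = 1L) {
  if (inherits(paths, "walk_path")) paths <- list(human = paths, robot = paths)
  speed_fn <- if (is.function(human_speed)) human_speed else function(t) human_speed
  set.seed(seed)
  n <- floor(duration / config$dt)
  s_h <- 0
  # robot starts d_r ahead of the human along its own path
  s_r <- config$d_r
  q0 <- paths$robot$point(s_r)
  q <- list(x = q0$x, y = q0$y, theta = q0$theta, t = 0)
  pi_st <- pi_state_init()
  rec <- matrix(NA_real_, n, 10)
  colnames(rec) <- c("t", "robot_x", "robot_y", "robot_theta", "human_x",
                     "human_y", "d_meas", "v_cmd", "omega_cmd", "integral")
  fov <- logical(n)
  half_apex <- config$fov_apex / 2 * pi / 180
  for (k in seq_len(n)) {
    hp <- paths$human$point(s_h)
    d_true <- sqrt((q$x - hp$x)^2 + (q$y - hp$y)^2)
    d_meas <- max(0, d_true + rnorm(1, 0, config$meas_noise_sd))
    ctrl <- pi_distance_control(d_meas, config, pi_st, config$dt)
    pi_st <- ctrl$state
    trk <- path_tracker(q, paths$robot, s_r, config)
    s_r <- trk$s
    u <- scale_control(trk$u, ctrl$v_pi)
    u$omega <- clamp(u$omega, -config$omega_max, config$omega_max)
    # FOV containment of the human in the rear camera cone
    rel <- c(hp$x - q$x, hp$y - q$y)
    back <- c(-cos(q$theta), -sin(q$theta))
    ang <- acos(clamp(sum(rel * back) / max(d_true, 1e-12), -1, 1))
    fov[k] <- d_true >= config$fov_near && d_true <= config$fov_far &&
      ang <= half_apex
    rec[k, ] <- c(q$t, q$x, q$y, q$theta, hp$x, hp$y, d_meas, u$v, u$omega,
                  pi_st$integral)
    q <- step_kinematics(q, u, config$dt)
    s_h <- s_h + speed_fn(q$t) * config$dt
  }
  series <- tibble::as_tibble(as.data.frame(rec))
  series$human_in_fov <- fov
  series$human_speed <- speed_fn(series$t)
  # robot ground speed from the recorded commands
  series$robot_speed <- series$v_cmd
  diverged <- mean(tail(series$d_meas, max(1, n %/% 4)) > 2 * config$d_r) > 0.5
  if (diverged) warn("distance controller diverged (persistent d > 2 d_r).")
  structure(list(series = series, config = config, diverged = diverged),
            class = "guided_walk")
}

#' Distance-keeping error metrics
#'
#' Mean absolute error and error standard deviation of the human-robot
#' distance (against `d_r`) and of the robot-human velocity difference,
#' computed after excluding the transient head and tail of the run
#' (defaults 15 s and 5 s).
#'
#' @param run A `guided_walk` from [simulate_guided_walk()], or a tibble
#'   with columns `t`, `d_meas`, `robot_speed`, `human_speed`.
#' @param config A [guidance_config()]; taken from `run` when omitted.
#' @return Tibble with `mae_distance`, `esd_distance`, `mae_velocity`,
#'   `esd_velocity` (m / m/s).
#' @export
error_metrics <- function(run, config = NULL) {
  if (inherits(run, "guided_walk")) {
    config <- config %||% run$config
    series <- run$series
  } else {
    series <- run
    config <- config %||% guidance_config()
  }
  check_columns(series, c("t", "d_meas", "robot_speed", "human_speed"),
                "series")
  t0 <- min(series$t) + config$transient_head
  t1 <- max(series$t) - config$transient_tail
  keep <- series$t >= t0 & series$t <= t1
  if (t1 <= t0 || !any(keep)) {
    abort("run too short: nothing remains after transient exclusion.",
          class = "gaitmos_input_error")
  }
  s <- series[keep, ]
  e_d <- s$d_meas - config$d_r
  e_v <- s$robot_speed - s$human_speed
  tibble::tibble(
    mae_distance = mean(abs(e_d)),
    esd_distance = sd(e_d) * sqrt((length(e_d) - 1) / length(e_d)),
    mae_velocity = mean(abs(e_v)),
    esd_velocity = sd(e_v) * sqrt((length(e_v) - 1) / length(e_v)))
}
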