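#' Inverted-pendulum body parameters
#'
#' The extrapolated centre of mass uses the inverted-pendulum eigenfrequency
#' `omega0 = sqrt(g / l)` with `l` the subject's leg length.
#'
#' @param leg_length Leg length `l` (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return A `body_params` list with `leg_length`, `g`, `omega0`.
#' @export
body_params <- function(leg_length = 0.9, g = 9.81) {
  check_number(leg_length, "leg_length", lower = 0, strict_lower = TRUE)
  check_number(g, "g", lower = 0, strict_lower = TRUE)
  structure(list(leg_length = leg_length, g = g,
                 omega0 = sqrt(g / leg_length)), class = "body_params")
}

#' Foot outline template
#'
#' A convex 8-vertex polygon approximating a shoe sole in the foot-local
#' frame (x forward, y left, origin under the sensor), scaled linearly from
#' shoe length. Used as the per-foot contribution to the base of support.
#'
#' @param length Shoe length (m).
#' @param width Shoe width (m); defaults to 0.38 of the length.
#' @return An n x 2 matrix of vertices (counter-clockwise, containing the
#'   origin).
#' @export
foot_outline <- function(length = 0.26, width = 0.38 * length) {
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  u <- length / 2
  w <- width / 2
  m <- matrix(c(
    -u, -0.6 * w,
    -0.6 * u, -w,
    0.6 * u, -w,
    u, -0.5 * w,
    u, 0.5 * w,
    0.6 * u, w,
    -0.6 * u, w,
    -u, 0.6 * w), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Transform a sensor-frame point to the world frame
#'
#' Applies the camera extrinsics (camera frame to robot frame) and then the
#' planar robot pose (robot frame to world frame).
#'
#' @param point Length-3 numeric, or an n x 3 matrix of points.
#' @param robot_pose List/row with `x`, `y`, `theta`.
#' @param extrinsics [rigid_transform()], camera -> robot.
#' @return Matrix (n x 3) of world-frame points (a length-3 vector input
#'   returns a 1 x 3 matrix).
#' @export
sensor_to_world <- function(point, robot_pose,
                            extrinsics = rigid_transform()) {
  if (!all(is.finite(c(robot_pose$x, robot_pose$y, robot_pose$theta)))) {
    abort("robot pose must be finite.", class = "gaitmos_input_error")
  }
  tf <- robot_pose_transform(robot_pose$x, robot_pose$y, robot_pose$theta)
  apply_rigid(tf, apply_rigid(extrinsics, point))
}

#' Estimate the centre of mass track from pelvis positions
#'
#' Projects the world-frame pelvis track onto the ground plane, smooths it
#' with a centred moving average, and differentiates it with centred finite
#' differences. Gaps (flagged by missing values) are linearly interpolated
#' up to `max_gap` seconds; longer gaps stay missing.
#'
#' @param pelvis Tibble with columns `t`, `x`, `y` (world frame, m).
#' @param smoothing Moving-average window (s).
#' @param max_gap Longest gap (s) bridged by interpolation.
#' @return Tibble `t`, `com_x`, `com_y`, `vcom_x`, `vcom_y`.
#' @export
estimate_com <- function(pelvis, smoothing = 0.15, max_gap = 0.5) {
  check_columns(pelvis, c("t", "x", "y"), "pelvis")
  check_time_sorted(pelvis$t, "pelvis")
  dt <- median(diff(pelvis$t))
  win <- max(1L, round(smoothing / dt))
  if (win %% 2 == 0) win <- win + 1L
  if (nrow(pelvis) <= win) {
    abort("pelvis track shorter than the smoothing window.",
          class = "gaitmos_input_error")
  }
  bridge <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- !is.na(v)
    filled <- approx(pelvis$t[ok], v[ok], pelvis$t, rule = 2)$y
    # re-blank gaps longer than max_gap
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      t0 <- pelvis$t[max(1L, starts[j] - 1L)]
      t1 <- pelvis$t[min(length(v), ends[j] + 1L)]
      if (t1 - t0 > max_gap) filled[starts[j]:ends[j]] <- NA_real_
    }
    filled
  }
  smooth <- function(v) {
    sm <- stats::filter(v, rep(1 / win, win), sides = 2)
    as.numeric(ifelse(is.na(sm), v, sm)) # fall back to raw at the edges
  }
  x <- smooth(bridge(pelvis$x))
  y <- smooth(bridge(pelvis$y))
  deriv <- function(v) {
    n <- length(v)
    d <- rep(NA_real_, n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (pelvis$t[3:n] - pelvis$t[1:(n - 2)])
    d[1] <- (v[2] - v[1]) / (pelvis$t[2] - pelvis$t[1])
    d[n] <- (v[n] - v[n - 1]) / (pelvis$t[n] - pelvis$t[n - 1])
    d
  }
  tibble::tibble(t = pelvis$t, com_x = x, com_y = y,
                 vcom_x = deriv(x), vcom_y = deriv(y))
}

#' Extrapolated centre of mass
#'
#' `xcom = com + vcom / omega0`, the inverted-pendulum extrapolation of the
#' centre of mass along its velocity.
#'
#' @param com Tibble/data frame with `com_x`, `com_y`, `vcom_x`, `vcom_y`
#'   (as from [estimate_com()]).
#' @param body A [body_params()].
#' @return Input with `xcom_x`, `xcom_y` appended.
#' @export
xcom <- function(com, body = body_params()) {
  check_columns(com, c("com_x", "com_y", "vcom_x", "vcom_y"), "com")
  dplyr::mutate(tibble::as_tibble(com),
                xcom_x = .data$com_x + .data$vcom_x / body$omega0,
                xcom_y = .data$com_y + .data$vcom_y / body$omega0)
}

#' Base of support polygon
#'
#' Transforms the foot outline by each in-contact foot's planar pose, pools
#' the vertices and returns their convex hull (counter-clockwise).
#'
#' @param foot_poses List with elements `left` and `right`, each a list/row
#'   with `x`, `y` and heading `theta` (rad); a foot absent or `NULL` is
#'   ignored.
#' @param contact Named logical vector `c(left = , right = )`.
#' @param outline Foot outline matrix from [foot_outline()].
#' @return An n x 2 matrix of hull vertices, or `NULL` when no foot is in
#'   contact (margin of stability undefined there).
#' @export
bos_polygon <- function(foot_poses, contact, outline = foot_outline()) {
  pts <- NULL
  for (side in c("left", "right")) {
    if (!isTRUE(contact[[side]])) next
    fp <- foot_poses[[side]]
    if (is.null(fp)) next
    ct <- cos(fp$theta); stn <- sin(fp$theta)
    rot <- cbind(outline[, 1] * ct - outline[, 2] * stn,
                 outline[, 1] * stn + outline[, 2] * ct)
    pts <- rbind(pts, sweep(rot, 2, c(fp$x, fp$y), `+`))
  }
  if (is.null(pts)) return(NULL)
  hull <- chull(pts) # clockwise from chull(); reverse for CCW
  pts[rev(hull), , drop = FALSE]
}

#' Signed distance from a point to a convex polygon boundary
#'
#' Positive when the point is strictly inside the polygon, negative outside,
#' zero on the boundary; magnitude is the Euclidean distance to the nearest
#' boundary point.
#'
#' @param point Length-2 numeric.
#' @param poly n x 2 vertex matrix of a convex polygon (any vertex order).
#' @return Signed distance (m).
#' @export
signed_distance <- function(point, poly) {
  poly <- unique(round(poly, 15))
  if (is.null(poly) || nrow(poly) < 3) {
    abort("polygon must have at least 3 distinct vertices.",
          class = "gaitmos_input_error")
  }
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  # distance point-to-segment for every edge
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  px <- point[1] - a[, 1]; py <- point[2] - a[, 2]
  tt <- clamp((px * ex + py * ey) / (ex^2 + ey^2), 0, 1)
  dx <- px - tt * ex; dy <- py - tt * ey
  dmin <- sqrt(min(dx^2 + dy^2))
  dmin * ifelse(point_in_convex(point, poly), 1, -1)
}

# inside test for convex polygons: consistent sign of all edge cross
# products (boundary counts as inside, distance there is 0 anyway)
point_in_convex <- function(point, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  cr <- (b[, 1] - a[, 1]) * (point[2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (point[1] - a[, 1])
  all(cr >= 0) || all(cr <= 0)
}

# Margin measured along an axis: intersect the line {p + s u} with the
# convex polygon. Inside: distance to the nearest boundary crossing along
# the axis (positive). Outside: minus the distance to the nearest crossing,
# or minus the Euclidean distance when the axis line misses the polygon.
directional_margin <- function(point, u, poly) {
  if (is.null(poly)) return(NA_real_)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  # orient inward normals (CCW polygon: inward normal is left of the edge)
  if (polygon_area(poly) < 0) { tmp <- a; a <- b; b <- tmp }
  nx <- -(b[, 2] - a[, 2]); ny <- b[, 1] - a[, 1]
  num <- nx * (point[1] - a[, 1]) + ny * (point[2] - a[, 2])
  den <- nx * u[1] + ny * u[2]
  smin <- -Inf; smax <- Inf
  for (i in seq_len(n)) {
    if (abs(den[i]) < 1e-14) {
      if (num[i] < 0) return(-signed_distance_abs(point, poly)) # line misses
    } else {
      s <- -num[i] / den[i]
      if (den[i] > 0) smin <- max(smin, s) else smax <- min(smax, s)
    }
  }
  if (smin > smax) return(-signed_distance_abs(point, poly))
  if (smin <= 0 && smax >= 0) min(smax, -smin) else -min(abs(smin), abs(smax))
}

signed_distance_abs <- function(point, poly) abs(signed_distance(point, poly))

polygon_area <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2]) / 2
}

#' Margin-of-stability track
#'
#' Computes, at every centre-of-mass sample, the extrapolated centre of
#' mass, the base of support from the feet currently in stance, and the
#' signed Euclidean margin of stability (positive when the XCoM is inside
#' the BoS). Stance comes from the insole events (load above threshold),
#' foot poses from the fused trajectories.
#'
#' @param com Tibble from [estimate_com()].
#' @param traj_left,traj_right Trajectories from [run_ekf()].
#' @param events Event table from [detect_gait_events()] for both feet.
#' @param body A [body_params()].
#' @param outline Foot outline matrix from [foot_outline()].
#' @return A `mos_track` tibble: `t`, `com_x/y`, `vcom_x/y`, `xcom_x/y`,
#'   `n_support`, `mos`, and a list-column `bos` of hull matrices.
#' @export
mos_track <- function(com, traj_left, traj_right, events,
                      body = body_params(), outline = foot_outline()) {
  xc <- xcom(com, body)
  stance_at <- function(ev, tq) {
    ev <- ev[ev$t <= tq, ]
    nrow(ev) > 0 && ev$kind[nrow(ev)] == "HS"
  }
  ev_l <- events[events$foot == "left", ] |> dplyr::arrange(.data$t)
  ev_r <- events[events$foot == "right", ] |> dplyr::arrange(.data$t)
  pose_from <- function(traj, tq) {
    s <- traj_at(traj, tq)
    list(x = s$x, y = s$y,
         theta = quat_yaw(c(s$qw, s$qx, s$qy, s$qz)))
  }
  res <- purrr::map(seq_len(nrow(xc)), function(i) {
    tq <- xc$t[i]
    contact <- c(left = stance_at(ev_l, tq), right = stance_at(ev_r, tq))
    if (!any(contact)) {
      return(list(bos = NULL, mos = NA_real_, n_support = 0L))
    }
    poly <- bos_polygon(
      list(left = pose_from(traj_left, tq), right = pose_from(traj_right, tq)),
      contact, outline)
    list(bos = poly,
         mos = signed_distance(c(xc$xcom_x[i], xc$xcom_y[i]), poly),
         n_support = sum(contact))
  })
  xc$n_support <- purrr::map_int(res, "n_support")
  xc$mos <- purrr::map_dbl(res, "mos")
  xc$bos <- purrr::map(res, "bos")
  class(xc) <- c("mos_track", class(xc))
  xc
}

#' Per-cycle margin-of-stability summary
#'
#' Resamples the margin track of one gait cycle onto 100 equally spaced
#' phase points (heel strike to next heel strike, linear interpolation) and
#' extracts the cycle scalars: `mos_ap` is the mean anteroposterior margin;
#' `mos_ml_pos` (`mos_ml_neg`) is the integral over normalised phase of the
#' positive (negative) part of the mediolateral margin. The anteroposterior
#' axis is the mean centre-of-mass velocity direction over the cycle; the
#' mediolateral axis is its left perpendicular. Margins along an axis are
#' boundary-crossing distances, positive towards the interior (see the
#' methods vignette). Setting `integrate_time = TRUE` integrates the
#' mediolateral parts over seconds instead of phase.
#'
#' @param track A [mos_track()] tibble (must cover the cycle).
#' @param cycle One stride row (fields `t_hs`, `t_next_hs`).
#' @param n_phase Number of phase points (100).
#' @param integrate_time Integrate ML parts over time (s x m) instead of
#'   normalised phase (m).
#' @return A `cycle_mos` list: scalars `mos_ap`, `mos_ml_pos`,
#'   `mos_ml_neg`, the `heading` vector, and `phase_series` (tibble with
#'   `phase`, `t`, `mos_ap`, `mos_ml`).
#' @export
cycle_mos <- function(track, cycle, n_phase = 100L, integrate_time = FALSE) {
  t0 <- cycle$t_hs; t1 <- cycle$t_next_hs
  if (min(track$t) > t0 || max(track$t) < t1) {
    abort(sprintf("margin track does not cover the cycle [%.3f, %.3f] s.", t0, t1),
          class = "gaitmos_input_error")
  }
  seg <- track[track$t >= t0 & track$t <= t1, ]
  hx <- mean(seg$vcom_x, na.rm = TRUE); hy <- mean(seg$vcom_y, na.rm = TRUE)
  hn <- sqrt(hx^2 + hy^2)
  if (!is.finite(hn) || hn < 1e-12) {
    abort("cycle has no net centre-of-mass motion; heading undefined.",
          class = "gaitmos_input_error")
  }
  ap <- c(hx, hy) / hn
  ml <- c(-ap[2], ap[1]) # left perpendicular
  m_ap <- purrr::map_dbl(seq_len(nrow(seg)), function(i) {
    directional_margin(c(seg$xcom_x[i], seg$xcom_y[i]), ap, seg$bos[[i]])
  })
  m_ml <- purrr::map_dbl(seq_len(nrow(seg)), function(i) {
    directional_margin(c(seg$xcom_x[i], seg$xcom_y[i]), ml, seg$bos[[i]])
  })
  phase <- seq(0, 1, length.out = n_phase)
  tq <- t0 + phase * (t1 - t0)
  ok <- is.finite(m_ap)
  series <- tibble::tibble(
    phase = phase, t = tq,
    mos_ap = approx(seg$t[ok], m_ap[ok], tq, rule = 2)$y,
    mos_ml = approx(seg$t[ok], m_ml[ok], tq, rule = 2)$y)
  scale <- if (integrate_time) (t1 - t0) else 1
  structure(list(
    mos_ap = mean(series$mos_ap),
    mos_ml_pos = mean(pmax(series$mos_ml, 0)) * scale,
    mos_ml_neg = mean(pmin(series$mos_ml, 0)) * scale,
    heading = ap, phase_series = series,
    t_hs = t0, t_next_hs = t1), class = "cycle_mos")
}

#' Margin-of-stability scalars for every stride
#'
#' Applies [cycle_mos()] to each stride covered by the track.
#'
#' @param track A [mos_track()].
#' @param strides Stride table (needs `foot`, `t_hs`, `t_next_hs`).
#' @param ... Passed to [cycle_mos()].
#' @return Tibble: `foot`, `stride`, `t_hs`, `mos_ap`, `mos_ml_pos`,
#'   `mos_ml_neg`.
#' @export
summarize_mos_cycles <- function(track, strides, ...) {
  keep <- strides$t_hs >= min(track$t) & strides$t_next_hs <= max(track$t)
  rows <- strides[keep, ]
  purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    cm <- cycle_mos(track, rows[i, ], ...)
    tibble::tibble(foot = rows$foot[i], stride = rows$stride[i],
                   t_hs = rows$t_hs[i], mos_ap = cm$mos_ap,
                   mos_ml_pos = cm$mos_ml_pos, mos_ml_neg = cm$mos_ml_neg)
  })
}
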