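# Internal helpers: argument checks, quaternions, rigid transforms.
#
# Quaternion convention throughout the package: Hamilton product, unit
# quaternions stored as c(w, x, y, z), mapping SENSOR frame vectors into the
# WORLD frame (right-handed, z up).

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gaitmos_config_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its valid range %s%g, %g%s.",
                  name, x, if (strict_lower) "(" else "[", lower, upper,
                  if (strict_upper) ")" else "]"),
          class = "gaitmos_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")),
          class = "gaitmos_input_error")
  }
  invisible(df)
}

check_time_sorted <- function(t, name, strict = TRUE) {
  d <- diff(t)
  bad <- if (strict) which(d <= 0) else which(d < 0)
  if (length(bad)) {
    abort(sprintf("`%s` timestamps are not %sincreasing at row %d.",
                  name, if (strict) "strictly " else "", bad[1] + 1L),
          class = "gaitmos_input_error")
  }
  invisible(t)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

## ---- quaternions (Hamilton, w-first, sensor -> world) ----------------------

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(phi) {
  angle <- sqrt(sum(phi^2))
  if (angle < 1e-12) {
    quat_normalize(c(1, phi / 2))
  } else {
    c(cos(angle / 2), sin(angle / 2) * phi / angle)
  }
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

quat_yaw <- function(q) {
  atan2(2 * (q[1] * q[4] + q[2] * q[3]), 1 - 2 * (q[3]^2 + q[4]^2))
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

## ---- rigid transforms ------------------------------------------------------

#' Build a rigid transform
#'
#' A rigid transform is a rotation followed by a translation, used for the
#' camera-to-robot extrinsics and for robot-to-world pose changes.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (metres).
#' @return An object of class `rigid_transform` (list with `R` and `t`).
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

apply_rigid <- function(tf, pts) {
  # pts: n x 3 matrix (or length-3 vector)
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  sweep(pts %*% t(tf$R), 2, tf$t, `+`)
}

invert_rigid <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

robot_pose_transform <- function(x, y, theta) {
  ct <- cos(theta); st <- sin(theta)
  rigid_transform(matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1),
                         nrow = 3, byrow = TRUE),
                  c(x, y, 0))
}
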