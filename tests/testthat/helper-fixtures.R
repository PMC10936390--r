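# Shared fixtures: trials are expensive enough to cache within a test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# noiseless trial: exact kinematics, near-noise-free camera, no dropout
noiseless_config <- function(n_strides = 8, seed = 3, cv = 2) {
  gait_sim_config(n_strides = n_strides, cv_sl = cv, cv_st = cv,
                  imu_noise_sd = c(0, 0), cam_noise_sd = 1e-6,
                  cam_dropout_prob = 0, seed = seed)
}

noiseless_trial <- function() {
  cached("noiseless_trial", simulate_walk(noiseless_config()))
}

noisy_trial <- function() {
  cached("noisy_trial", simulate_walk(gait_sim_config(n_strides = 8, seed = 3)))
}

# run the event -> EKF -> spatial chain for one trial
fuse_trial <- function(trial, ekfc = ekf_config()) {
  res <- list()
  for (f in c("left", "right")) {
    ins <- trial[[paste0("insole_", f)]]
    cam <- trial$camera[trial$camera$target == paste0(f, "_foot"), ]
    ff <- detect_foot_flat(ins, ekfc)
    traj <- suppressMessages(
      run_ekf(ins, cam, trial$robot_pose, ekfc, trial$config$extrinsics,
              ff = ff))
    res[[f]] <- list(traj = traj, ff = ff)
  }
  events <- dplyr::bind_rows(detect_gait_events(trial$insole_left),
                             detect_gait_events(trial$insole_right))
  strides <- temporal_parameters(events)
  strides <- suppressMessages(
    spatial_parameters(strides, res$left$traj, res$right$traj,
                       res$left$ff, res$right$ff))
  list(events = events, strides = strides,
       traj_left = res$left$traj, traj_right = res$right$traj,
       ff_left = res$left$ff, ff_right = res$right$ff)
}

fused_noiseless <- function() {
  cached("fused_noiseless",
         fuse_trial(noiseless_trial(), ekf_config(cam_pos_noise_sd = 1e-4)))
}

# --- independent signed-distance oracle -------------------------------------
# Sign by ray casting (crossing parity on a horizontal ray), magnitude by
# 1-D minimisation of the Euclidean distance along each edge. Shares no code
# with signed_distance().
oracle_signed_distance <- function(point, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  crossings <- 0L
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[nxt[i], 1]; y2 <- poly[nxt[i], 2]
    if ((y1 > point[2]) != (y2 > point[2])) {
      xi <- x1 + (point[2] - y1) / (y2 - y1) * (x2 - x1)
      if (xi > point[1]) crossings <- crossings + 1L
    }
  }
  inside <- crossings %% 2L == 1L
  dmin <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    f <- function(s) {
      q <- a + s * (b - a)
      sqrt(sum((point - q)^2))
    }
    o <- optimize(f, c(0, 1), tol = 1e-12)
    dmin <- min(dmin, o$objective, f(0), f(1))
  }
  if (inside) dmin else -dmin
}

random_convex_polygon <- function(n_max = 10) {
  repeat {
    k <- sample(3:n_max, 1)
    pts <- matrix(runif(2 * k, -1, 1), ncol = 2)
    h <- chull(pts)
    if (length(h) >= 3) return(pts[h, , drop = FALSE])
  }
}

expect_psd <- function(P) {
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
}

# rigidly transform all world-frame inputs of a trial fusion (planar)
rotate_xy <- function(m, ang, shift = c(0, 0)) {
  ct <- cos(ang); st <- sin(ang)
  cbind(ct * m[, 1] - st * m[, 2] + shift[1],
        st * m[, 1] + ct * m[, 2] + shift[2])
}
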