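# Stream readers/writers. All files are RFC-4180 CSV with SI units
# (metres, seconds, m/s, rad); percent columns carry the `_pct` suffix;
# timestamps are seconds from trial start.

stream_schemas <- list(
  insole = c("t", paste0("fsr", 1:8), "ax", "ay", "az", "gx", "gy", "gz",
             "foot"),
  camera = c("t", "target", "x", "y", "z", "qw", "qx", "qy", "qz", "valid"),
  robot_pose = c("t", "x", "y", "theta"),
  events = c("foot", "kind", "t", "index"),
  strides = c("foot", "stride", "t_hs", "t_to", "t_next_hs", "st", "swing",
              "swp", "sl", "sv", "sw"),
  trajectory = c("t", "x", "y", "z", "vx", "vy", "vz", "qw", "qx", "qy",
                 "qz", "trace_P"),
  mos = c("t", "com_x", "com_y", "xcom_x", "xcom_y", "mos"),
  cycles = c("foot", "stride", "t_hs", "mos_ap", "mos_ml_pos", "mos_ml_neg"))

#' Read a validated stream CSV
#'
#' Reads one of the package's stream/table formats and validates it:
#' required columns present, numeric columns numeric, and (for timestamped
#' streams) strictly increasing time within each foot/target group. Errors
#' name the first offending row.
#'
#' @param path CSV file path.
#' @param schema One of `"insole"`, `"camera"`, `"robot_pose"`, `"events"`,
#'   `"strides"`, `"trajectory"`, `"mos"`, `"cycles"`.
#' @return A tibble.
#' @export
read_stream <- function(path, schema = names(stream_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "gaitmos_input_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- stream_schemas[[schema]]
  check_columns(df, required, path)
  if (nrow(df) == 0) return(df) # header-only file: empty stream, no error
  num_cols <- setdiff(required, c("foot", "kind", "target", "valid"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
      abort(sprintf("%s: column `%s` is not numeric (first offending row %d).",
                    path, cl, bad %||% 1L), class = "gaitmos_input_error")
    }
  }
  if ("t" %in% required && nrow(df) > 1) {
    grp <- if ("target" %in% names(df)) df$target
    else if ("foot" %in% names(df) && schema == "insole") df$foot
    else rep(1L, nrow(df))
    for (g in unique(grp)) {
      tt <- df$t[grp == g]
      d <- diff(tt)
      bad <- which(d <= 0)
      if (length(bad)) {
        abort(sprintf("%s: timestamps not strictly increasing at row %d.",
                      path, which(grp == g)[bad[1] + 1L]),
              class = "gaitmos_input_error")
      }
    }
  }
  df
}

#' Write a stream CSV
#'
#' @param df Data frame/tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Serialize a synthetic trial to a directory
#'
#' Writes `insole_left.csv`, `insole_right.csv`, `camera.csv`,
#' `robot_pose.csv`, the truth tables, and the configuration as a flat
#' key-value file.
#'
#' @param trial A `gait_trial` from [simulate_walk()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stream(trial$insole_left, file.path(dir, "insole_left.csv"))
  write_stream(trial$insole_right, file.path(dir, "insole_right.csv"))
  write_stream(trial$camera, file.path(dir, "camera.csv"))
  write_stream(trial$robot_pose, file.path(dir, "robot_pose.csv"))
  write_stream(trial$truth$events, file.path(dir, "truth_events.csv"))
  write_stream(trial$truth$strides, file.path(dir, "truth_strides.csv"))
  cfg <- trial$config
  scalars <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 1,
                        logical(1))]
  writeLines(paste(names(scalars), unlist(scalars), sep = " = "),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Run the full gait-analysis pipeline
#'
#' End-to-end composition: event detection on both insoles, temporal
#' parameters, foot-flat detection, EKF fusion, spatial parameters, centre
#' of mass and margin-of-stability track, per-cycle margins, and per-trial
#' summaries. Inputs are either a synthetic trial (generated in place) or a
#' directory of stream CSVs.
#'
#' @param trial A `gait_trial`, or a directory path containing
#'   `insole_left.csv`, `insole_right.csv`, `camera.csv`, `robot_pose.csv`.
#' @param sim_config [gait_sim_config()] used when `trial` is `NULL`.
#' @param fsr_config [fsr_threshold_config()].
#' @param ekf_cfg [ekf_config()].
#' @param body [body_params()]; defaults to the simulated leg length when a
#'   synthetic trial is supplied.
#' @param outline [foot_outline()] matrix.
#' @param allow_degraded Proceed without a camera stream (IMU + ZUPT only).
#' @param out_dir Optional directory: all intermediate tables and a JSON
#'   report are written there.
#' @return A `gait_report` list: `events`, `strides`, `ff`, `traj_left`,
#'   `traj_right`, `mos`, `cycles`, `summary`, `meta`.
#' @export
run_pipeline <- function(trial = NULL, sim_config = gait_sim_config(),
                         fsr_config = fsr_threshold_config(),
                         ekf_cfg = ekf_config(), body = NULL,
                         outline = foot_outline(), allow_degraded = FALSE,
                         out_dir = NULL) {
  if (is.null(trial)) trial <- simulate_walk(sim_config)
  if (is.character(trial)) {
    dir <- trial
    need <- c("insole_left.csv", "insole_right.csv", "robot_pose.csv")
    for (f in need) {
      if (!file.exists(file.path(dir, f))) {
        abort(sprintf("pipeline stage `load`: missing input %s in %s.", f, dir),
              class = "gaitmos_input_error")
      }
    }
    cam_path <- file.path(dir, "camera.csv")
    if (!file.exists(cam_path) && !allow_degraded) {
      abort("pipeline stage `load`: camera.csv missing (use allow_degraded to run IMU+ZUPT only).",
            class = "gaitmos_input_error")
    }
    trial <- list(
      insole_left = read_stream(file.path(dir, "insole_left.csv"), "insole"),
      insole_right = read_stream(file.path(dir, "insole_right.csv"), "insole"),
      camera = if (file.exists(cam_path)) read_stream(cam_path, "camera")
      else NULL,
      robot_pose = read_stream(file.path(dir, "robot_pose.csv"), "robot_pose"),
      config = NULL)
  }
  body <- body %||% body_params(trial$config$leg_length %||% 0.9)
  extr <- trial$config$extrinsics %||% rigid_transform()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), class = "gaitmos_pipeline_error")
    })
  }
  events <- stage("events", dplyr::bind_rows(
    detect_gait_events(trial$insole_left, fsr_config),
    detect_gait_events(trial$insole_right, fsr_config)))
  strides <- stage("temporal", temporal_parameters(events))
  ff_l <- stage("foot_flat", detect_foot_flat(trial$insole_left, ekf_cfg))
  ff_r <- stage("foot_flat", detect_foot_flat(trial$insole_right, ekf_cfg))
  cam_for <- function(target) {
    if (is.null(trial$camera)) NULL
    else trial$camera[trial$camera$target == target, ]
  }
  traj_l <- stage("ekf", run_ekf(trial$insole_left, cam_for("left_foot"),
                                 trial$robot_pose, ekf_cfg, extr, ff = ff_l))
  traj_r <- stage("ekf", run_ekf(trial$insole_right, cam_for("right_foot"),
                                 trial$robot_pose, ekf_cfg, extr, ff = ff_r))
  strides <- stage("spatial",
                   spatial_parameters(strides, traj_l, traj_r, ff_l, ff_r))

  mos <- cycles <- NULL
  pelvis_cam <- cam_for("pelvis")
  if (!is.null(pelvis_cam) && nrow(pelvis_cam)) {
    pelvis_world <- stage("com", {
      pc <- pelvis_cam[pelvis_cam$valid, ]
      w <- t(vapply(seq_len(nrow(pc)), function(i) {
        pose <- list(
          x = approx(trial$robot_pose$t, trial$robot_pose$x, pc$t[i], rule = 2)$y,
          y = approx(trial$robot_pose$t, trial$robot_pose$y, pc$t[i], rule = 2)$y,
          theta = approx(trial$robot_pose$t, trial$robot_pose$theta, pc$t[i],
                         rule = 2)$y)
        as.numeric(sensor_to_world(c(pc$x[i], pc$y[i], pc$z[i]), pose, extr))
      }, numeric(3)))
      tibble::tibble(t = pc$t, x = w[, 1], y = w[, 2], z = w[, 3])
    })
    com <- stage("com", estimate_com(pelvis_world))
    mos <- stage("mos", mos_track(com, traj_l, traj_r, events, body, outline))
    cycles <- stage("mos", summarize_mos_cycles(mos, strides))
  }

  summary <- stage("summary", {
    strides |>
      dplyr::group_by(.data$foot) |>
      dplyr::group_modify(~summarize_trial(
        .x, cycles = if (is.null(cycles)) NULL
        else cycles[cycles$foot == .y$foot, ])) |>
      dplyr::ungroup()
  })

  report <- list(events = events, strides = strides,
                 ff = dplyr::bind_rows(ff_l, ff_r),
                 traj_left = traj_l, traj_right = traj_r,
                 mos = mos, cycles = cycles, summary = summary,
                 meta = list(
                   package_version = as.character(utils::packageVersion("gaitmos")),
                   seed = trial$config$seed %||% NA,
                   n_events = nrow(events), n_strides = nrow(strides),
                   report_schema = "gaitmos-report/1"))
  class(report) <- "gait_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stream(events, file.path(out_dir, "events.csv"))
    write_stream(strides, file.path(out_dir, "strides.csv"))
    write_stream(dplyr::select(traj_l, -dplyr::any_of("bos")),
                 file.path(out_dir, "trajectory_left.csv"))
    write_stream(dplyr::select(traj_r, -dplyr::any_of("bos")),
                 file.path(out_dir, "trajectory_right.csv"))
    if (!is.null(mos)) {
      write_stream(dplyr::select(mos, -"bos"), file.path(out_dir, "mos.csv"))
      write_stream(cycles, file.path(out_dir, "mos_cycles.csv"))
    }
    write_stream(summary, file.path(out_dir, "summary.csv"))
    json <- list(schema = report$meta$report_schema,
                 meta = report$meta[c("package_version", "seed", "n_events",
                                      "n_strides")],
                 summary = summary)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>", x$meta$n_strides, "strides,", x$meta$n_events,
      "events\n")
  print(x$summary)
  invisible(x)
}
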