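# ggplot2 displays for the main result types.

#' Plot a synthetic trial's insole load and events
#'
#' Total insole load per foot over time, with detected (or ground-truth)
#' heel-strike/toe-off events overlaid.
#'
#' @param object A `gait_trial`.
#' @param events Optional event table; defaults to the trial's ground truth.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, events = NULL, ...) {
  events <- events %||% object$truth$events
  load <- dplyr::bind_rows(total_load(object$insole_left),
                           total_load(object$insole_right))
  ggplot2::ggplot(load, ggplot2::aes(x = .data$t, y = .data$load)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$t,
                                     colour = .data$kind),
                        linewidth = 0.2, alpha = 0.6) +
    ggplot2::facet_wrap(~foot, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "total load (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fused foot trajectories over ground-plane coordinates
#'
#' @param traj_left,traj_right `foot_trajectory` tibbles from [run_ekf()].
#' @return A ggplot object.
#' @export
plot_foot_trajectories <- function(traj_left, traj_right) {
  df <- dplyr::bind_rows(
    dplyr::mutate(traj_left, foot = "left"),
    dplyr::mutate(traj_right, foot = "right"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$foot)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the phase-normalised margin-of-stability profile
#'
#' Mean (and per-cycle spaghetti) of the anteroposterior and mediolateral
#' margins over the 100-point normalised gait cycle.
#'
#' @param track A `mos_track`.
#' @param strides Stride table covering the track.
#' @param ... Passed to [cycle_mos()].
#' @return A ggplot object.
#' @export
plot_mos_cycles <- function(track, strides, ...) {
  keep <- strides$t_hs >= min(track$t) & strides$t_next_hs <= max(track$t)
  rows <- strides[keep, ]
  series <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    cm <- cycle_mos(track, rows[i, ], ...)
    dplyr::mutate(cm$phase_series, cycle = i, foot = rows$foot[i])
  })
  long <- tidyr::pivot_longer(series, c("mos_ap", "mos_ml"),
                              names_to = "axis", values_to = "margin")
  ggplot2::ggplot(long, ggplot2::aes(x = 100 * .data$phase, y = .data$margin,
                                     group = .data$cycle)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.2) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", colour = "red", linewidth = 0.7) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = "margin of stability (m)") +
    ggplot2::theme_minimal()
}

#' Plot a guided-walk simulation
#'
#' Top: robot and human ground tracks. Bottom: measured human-robot
#' distance against the desired distance.
#'
#' @param object A `guided_walk` from [simulate_guided_walk()].
#' @param ... Unused.
#' @return A ggplot object (tracks); the distance series is attached as
#'   attribute `"distance_plot"`.
#' @export
autoplot.guided_walk <- function(object, ...) {
  s <- object$series
  tracks <- dplyr::bind_rows(
    tibble::tibble(t = s$t, x = s$robot_x, y = s$robot_y, who = "robot"),
    tibble::tibble(t = s$t, x = s$human_x, y = s$human_y, who = "human"))
  p1 <- ggplot2::ggplot(tracks, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$who)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = NULL) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(s, ggplot2::aes(x = .data$t, y = .data$d_meas)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$config$d_r, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "human-robot distance (m)") +
    ggplot2::theme_minimal()
  attr(p1, "distance_plot") <- p2
  p1
}
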