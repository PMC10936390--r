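#' Total insole load
#'
#' Sums the eight force-sensitive-resistor channels of an insole stream.
#'
#' @param insole Data frame with columns `fsr1` ... `fsr8` (non-negative,
#'   calibrated load units).
#' @return The input as a tibble with a `load` column appended.
#' @examples
#' df <- tibble::tibble(t = 0:1 / 100)
#' df[paste0("fsr", 1:8)] <- as.list(1:8)
#' total_load(df)$load # 36 36
#' @export
total_load <- function(insole) {
  check_columns(insole, paste0("fsr", 1:8), "insole")
  fsr <- as.matrix(insole[paste0("fsr", 1:8)])
  if (any(fsr < 0)) {
    abort("FSR channels must be non-negative.", class = "gaitmos_input_error")
  }
  dplyr::mutate(tibble::as_tibble(insole), load = rowSums(fsr))
}

#' Threshold configuration for insole event detection
#'
#' Heel strike is detected when the total load rises through
#' `threshold + hysteresis/2`, toe off when it falls through
#' `threshold - hysteresis/2`. Candidate stance (swing) intervals shorter
#' than `min_stance` (`min_swing`) are treated as sensor chatter and merged
#' away. When `threshold` is `NULL` a self-scaling rule is used: 5% of the
#' trial's 95th-percentile total load, with hysteresis 1% of the same scale,
#' so synthetic and real load units both work without calibration.
#'
#' @param threshold Crossing level in load units, or `NULL` for the
#'   self-scaling rule.
#' @param hysteresis Width of the hysteresis band (load units), or `NULL`
#'   to scale it with the automatic threshold.
#' @param min_stance,min_swing Minimum stance/swing duration (s) kept by the
#'   debouncer.
#' @return An `fsr_threshold_config` list.
#' @export
fsr_threshold_config <- function(threshold = NULL, hysteresis = NULL,
                                 min_stance = 0.1, min_swing = 0.1) {
  if (!is.null(threshold)) check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  if (!is.null(hysteresis)) check_number(hysteresis, "hysteresis", lower = 0)
  check_number(min_stance, "min_stance", lower = 0)
  check_number(min_swing, "min_swing", lower = 0)
  structure(list(threshold = threshold, hysteresis = hysteresis,
                 min_stance = min_stance, min_swing = min_swing),
            class = "fsr_threshold_config")
}

resolve_threshold <- function(load, config) {
  scale <- quantile(load, 0.95, names = FALSE)
  thr <- config$threshold %||% (0.05 * scale)
  hys <- config$hysteresis %||% (0.01 * scale)
  if (thr <= 0) {
    abort("Resolved threshold is not positive; supply `threshold` explicitly.",
          class = "gaitmos_config_error")
  }
  list(threshold = thr, hysteresis = min(hys, 2 * thr * 0.999))
}

#' Detect heel-strike and toe-off events from insole load
#'
#' Runs a hysteresis threshold-crossing state machine on the summed FSR
#' channels of one foot's insole stream, debounces short stance/swing
#' candidates, and returns alternating HS/TO events starting at the first
#' heel strike. Event time is the timestamp of the first sample beyond the
#' crossing level (no sub-sample interpolation).
#'
#' @param insole One foot's insole stream: columns `t`, `fsr1` ... `fsr8`,
#'   and optionally `foot`. Timestamps must be strictly increasing.
#' @param config An [fsr_threshold_config()].
#' @return Tibble with columns `foot`, `kind` ("HS"/"TO"), `t`, `index`
#'   (1-based sample index), alternating HS, TO, HS, ...
#' @export
detect_gait_events <- function(insole, config = fsr_threshold_config()) {
  check_columns(insole, c("t", paste0("fsr", 1:8)), "insole")
  if (nrow(insole) == 0) {
    return(tibble::tibble(foot = character(), kind = character(),
                          t = numeric(), index = integer()))
  }
  check_time_sorted(insole$t, "insole")
  foot <- if ("foot" %in% names(insole)) {
    u <- unique(insole$foot)
    if (length(u) != 1) {
      abort("`insole` must contain a single foot; split the stream first.",
            class = "gaitmos_input_error")
    }
    u
  } else NA_character_
  load <- total_load(insole)$load
  if (all(load == 0)) {
    return(tibble::tibble(foot = character(), kind = character(),
                          t = numeric(), index = integer()))
  }
  lv <- resolve_threshold(load, config)
  hi <- lv$threshold + lv$hysteresis / 2
  lo <- lv$threshold - lv$hysteresis / 2

  # hysteresis state machine -> candidate stance intervals [on, off)
  state <- load[1] >= hi
  on_idx <- if (state) 1L else integer()
  off_idx <- integer()
  for (i in 2:length(load)) {
    if (!state && load[i] >= hi) {
      state <- TRUE
      on_idx <- c(on_idx, i)
    } else if (state && load[i] <= lo) {
      state <- FALSE
      off_idx <- c(off_idx, i)
    }
  }
  if (state) off_idx <- c(off_idx, NA_integer_) # open stance at stream end

  stances <- tibble::tibble(on = on_idx, off = off_idx)
  t <- insole$t
  dur <- function(i0, i1) ifelse(is.na(i1), Inf, t[i1] - t[i0])

  # debounce: first merge short swing gaps (join adjacent stances), then
  # drop short stance islands
  k <- 1L
  while (k < nrow(stances)) {
    gap <- t[stances$on[k + 1]] - t[stances$off[k]]
    if (gap < config$min_swing) {
      stances$off[k] <- stances$off[k + 1]
      stances <- stances[-(k + 1L), ]
    } else k <- k + 1L
  }
  keep <- dur(stances$on, stances$off) >= config$min_stance
  stances <- stances[keep, , drop = FALSE]
  if (!nrow(stances)) {
    return(tibble::tibble(foot = character(), kind = character(),
                          t = numeric(), index = integer()))
  }

  ev <- dplyr::bind_rows(
    tibble::tibble(kind = "HS", index = stances$on),
    tibble::tibble(kind = "TO", index = stances$off)) |>
    dplyr::filter(!is.na(.data$index)) |>
    dplyr::arrange(.data$index) |>
    dplyr::mutate(foot = foot, t = t[.data$index], .before = 1)
  ev[c("foot", "kind", "t", "index")]
}

#' Temporal gait parameters from alternating events
#'
#' Builds one stride per (HS, TO, next HS) triple of the same foot:
#' stride time `st = t_next_hs - t_hs`, swing time
#' `swing = t_next_hs - t_to`, and swing percent `swp = 100 * swing / st`.
#' Incomplete trailing triples are dropped.
#'
#' @param events Tibble as returned by [detect_gait_events()] (columns
#'   `foot`, `kind`, `t`; events must alternate HS, TO, ... per foot).
#' @return Tibble with one row per stride: `foot`, `stride`, `t_hs`, `t_to`,
#'   `t_next_hs`, `st`, `swing`, `swp`, plus empty spatial columns `sl`,
#'   `sv`, `sw` to be filled by [spatial_parameters()].
#' @export
temporal_parameters <- function(events) {
  check_columns(events, c("foot", "kind", "t"), "events")
  one_foot <- function(ev) {
    if (nrow(ev) == 0) return(NULL)
    check_time_sorted(ev$t, "events")
    expected <- rep(c("HS", "TO"), length.out = nrow(ev))
    bad <- which(ev$kind != expected)
    if (length(bad)) {
      abort(sprintf("events do not alternate HS/TO: unexpected %s at position %d.",
                    ev$kind[bad[1]], bad[1]),
            class = "gaitmos_input_error")
    }
    n_str <- (nrow(ev) - 1L) %/% 2L
    if (n_str < 1) return(NULL)
    hs <- ev$t[seq(1, by = 2, length.out = n_str + 1L)]
    to <- ev$t[seq(2, by = 2, length.out = n_str)]
    tibble::tibble(
      foot = ev$foot[1], stride = seq_len(n_str),
      t_hs = hs[1:n_str], t_to = to, t_next_hs = hs[-1],
      st = diff(hs), swing = hs[-1] - to,
      swp = 100 * (hs[-1] - to) / diff(hs),
      sl = NA_real_, sv = NA_real_, sw = NA_real_)
  }
  out <- events |>
    dplyr::group_by(.data$foot) |>
    dplyr::group_split() |>
    purrr::map(one_foot) |>
    dplyr::bind_rows()
  if (!nrow(out)) {
    out <- tibble::tibble(foot = character(), stride = integer(),
                          t_hs = numeric(), t_to = numeric(),
                          t_next_hs = numeric(), st = numeric(),
                          swing = numeric(), swp = numeric(),
                          sl = numeric(), sv = numeric(), sw = numeric())
  }
  out
}
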