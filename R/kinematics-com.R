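# Whole-body centre of mass and the COM-derived per-trial indices.

#' Whole-body centre of mass trajectory
#'
#' Weighted average of the ten segment centres of mass. Each segment COM is
#' placed at `com_frac` along the proximal-to-distal axis resolved from the
#' marker centroids in the segment table; the whole-body COM is the
#' mass-fraction weighted sum. The laboratory y-axis is the forward axis
#' (forward positive).
#'
#' @param markers marker tibble (gap-filled / ASIS-reconstructed).
#' @param segments body segment parameter table ([de_leva_segments()]).
#' @return tibble `time_s`, `com_x`, `com_y`, `com_z` (metres).
#' @export
whole_body_com <- function(markers, segments = de_leva_segments()) {
  validate_segments(segments)
  needed <- unique(unlist(c(segments$proximal, segments$distal)))
  cols <- paste0(rep(needed, each = 3), "_", c("x", "y", "z"))
  missing_cols <- setdiff(cols, names(markers))
  abort_if(length(missing_cols) > 0,
           paste("markers lack columns:",
                 paste(missing_cols, collapse = ", ")))
  na_marker <- needed[vapply(needed, function(m) {
    anyNA(markers[[paste0(m, "_x")]])
  }, logical(1))]
  if (length(na_marker) > 0) {
    bad_seg <- segments$segment[vapply(seq_len(nrow(segments)), function(i) {
      any(c(segments$proximal[[i]], segments$distal[[i]]) %in% na_marker)
    }, logical(1))]
    rlang::abort(paste0(
      "unresolvable landmarks for segment(s): ",
      paste(unique(bad_seg), collapse = ", "),
      " (missing marker samples; interpolate or reconstruct first)"),
      class = "standgaze_landmark_error")
  }
  M <- as.data.frame(markers[cols])
  com <- com_from_matrix(M, segments)
  tibble::tibble(time_s = markers$time_s %||% seq_len(nrow(markers)),
                 com_x = unname(com[, "x"]), com_y = unname(com[, "y"]),
                 com_z = unname(com[, "z"]))
}

#' Signed COM-to-BOS distance at seat-off
#'
#' Forward (y) distance from the trailing edge of the base of support -- the
#' rearmost heel marker -- to the whole-body COM at the seat-off instant.
#' Negative values mean the COM is behind the heel line.
#'
#' @param markers marker tibble.
#' @param com COM tibble from [whole_body_com()] (computed if `NULL`).
#' @param t_seat_off seat-off time(s) in seconds (vectorised over cycles).
#' @param segments segment table, used when `com` is `NULL`.
#' @return numeric vector of signed distances (m), one per seat-off time.
#' @export
com_bos_distance <- function(markers, t_seat_off, com = NULL,
                             segments = de_leva_segments()) {
  if (is.null(com)) com <- whole_body_com(markers, segments)
  vapply(t_seat_off, function(ts) {
    com_y <- stats::approx(com$time_s, com$com_y, xout = ts)$y
    heel_y <- min(stats::approx(markers$time_s, markers$LHEE_y, xout = ts)$y,
                  stats::approx(markers$time_s, markers$RHEE_y, xout = ts)$y)
    com_y - heel_y
  }, numeric(1))
}

#' Mean forward COM velocity over the rise window
#'
#' Forward COM displacement between seat-off and maximum ankle dorsiflexion
#' divided by the window length, per cycle.
#'
#' @param com COM tibble from [whole_body_com()].
#' @param t_seat_off,t_max_dorsi event times (s), one per cycle.
#' @return numeric vector of velocities (m/s), one per cycle.
#' @export
com_velocity <- function(com, t_seat_off, t_max_dorsi) {
  abort_if(length(t_seat_off) != length(t_max_dorsi),
           "event vectors must have equal length")
  abort_if(any(t_max_dorsi <= t_seat_off),
           "maximum dorsiflexion must occur after seat-off (zero-length window)",
           class = "standgaze_validation_error")
  y0 <- stats::approx(com$time_s, com$com_y, xout = t_seat_off)$y
  y1 <- stats::approx(com$time_s, com$com_y, xout = t_max_dorsi)$y
  (y1 - y0) / (t_max_dorsi - t_seat_off)
}

#' Deepest trunk flexion per cycle
#'
#' Per-cycle maximum of the trunk flexion angle; the trial-level index is the
#' mean over cycles.
#'
#' @param angle tibble `time_s`, `angle_deg` from [trunk_angle()].
#' @param cycle_windows tibble with `start_s`, `end_s` per cycle.
#' @return tibble `cycle`, `deepest_deg`, `t_peak_s`.
#' @export
deepest_trunk_flexion <- function(angle, cycle_windows) {
  purrr::map_dfr(seq_len(nrow(cycle_windows)), function(k) {
    idx <- angle$time_s >= cycle_windows$start_s[k] &
      angle$time_s <= cycle_windows$end_s[k]
    abort_if(!any(idx), "cycle window outside the angle series")
    a <- angle$angle_deg[idx]
    i <- which.max(a)
    tibble::tibble(cycle = k, deepest_deg = a[i],
                   t_peak_s = angle$time_s[idx][i])
  })
}
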