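# End-to-end per-trial pipelines: preprocessing -> kinematic indices, and
# fixation detection -> AOI metrics.

#' Full kinematic pipeline for one trial
#'
#' Synchronises the force plates onto the marker clock, fills short marker
#' gaps, low-passes markers (6 Hz) and forces (18 Hz) with the zero-phase
#' Butterworth filter, reconstructs occluded ASIS markers from the sacral
#' jig, then extracts per-cycle seat-off, maximum dorsiflexion, deepest
#' trunk flexion, COM-BOS distance at seat-off and forward COM velocity.
#' The trial-level index is the mean over cycles.
#'
#' @param trial an `sg_trial` (or a list with `markers`, `grf`, `meta`).
#' @param marker_cutoff_hz,grf_cutoff_hz,filter_order smoothing parameters.
#' @param max_gap_s longest marker gap filled by spline.
#' @param epsilon_n,debounce_s seat-off detector settings.
#' @param segments body segment parameter table.
#' @return list with `cycles` (per-cycle indices) and `summary` (one-row
#'   tibble of trial-level indices).
#' @export
trial_kinematics <- function(trial, marker_cutoff_hz = 6,
                             grf_cutoff_hz = 18, filter_order = 4,
                             max_gap_s = 0.2, epsilon_n = 5,
                             debounce_s = 0.05,
                             segments = de_leva_segments()) {
  markers <- trial$markers
  grf <- synchronize(trial$grf, markers)
  markers <- interpolate_gaps(markers, max_gap_s)
  markers <- lowpass_filter(markers, marker_cutoff_hz, order = filter_order)
  grf <- lowpass_filter(grf, grf_cutoff_hz, order = filter_order)

  pose <- calibrate_virtual_asis(.sg_first_complete_frame(markers))
  markers <- reconstruct_asis(markers, pose)

  expected <- trial$meta$script$cycles %||% NULL
  events <- detect_seat_off(grf, rear_plates = trial$meta$rear_plates,
                            epsilon_n = epsilon_n,
                            debounce_s = debounce_s, expected = expected)
  ankle <- ankle_angle(markers)
  dorsi <- detect_max_dorsiflexion(ankle, events)
  trunk <- trunk_angle(markers)
  com <- whole_body_com(markers, segments)

  vel <- com_velocity(com, events$seat_off_s, dorsi$t_max_dorsi_s)
  bos <- com_bos_distance(markers, events$seat_off_s, com = com)
  cw <- cycle_windows(events, min(markers$time_s), max(markers$time_s))
  deep <- deepest_trunk_flexion(trunk, cw)

  cycles <- tibble::tibble(
    cycle = events$cycle,
    seat_off_s = events$seat_off_s,
    t_max_dorsi_s = dorsi$t_max_dorsi_s,
    deepest_trunk_deg = deep$deepest_deg,
    com_bos_m = bos,
    com_velocity_ms = vel)
  summary <- tibble::tibble(
    n_cycles = nrow(cycles),
    deepest_trunk_deg = mean(cycles$deepest_trunk_deg),
    com_bos_m = mean(cycles$com_bos_m),
    com_velocity_ms = mean(cycles$com_velocity_ms),
    seat_off_s = cycles$seat_off_s[1],
    max_dorsiflexion_s = cycles$t_max_dorsi_s[1],
    asis_rms_m = attr(markers, "asis_quality"))
  list(cycles = cycles, summary = summary)
}

# First frame in which every marker coordinate is present.
.sg_first_complete_frame <- function(markers) {
  cols <- grep("_(x|y|z)$", names(markers), value = TRUE)
  ok <- stats::complete.cases(markers[cols])
  abort_if(!any(ok), "no frame with all markers visible",
           class = "standgaze_validation_error")
  markers[which(ok)[1], ]
}

#' Full gaze pipeline for one trial
#'
#' Low-passes the markers, derives the AOI layout and the support period,
#' runs the I-VT fixation filter on the gaze stream and computes the four
#' AOI metrics.
#'
#' @param trial an `sg_trial`.
#' @param velocity_threshold_dps,min_duration_ms I-VT settings.
#' @param chin_offset_m chin boundary offset for the head AOI.
#' @return tibble `aoi` x four metrics (one row per AOI).
#' @export
trial_gaze_metrics <- function(trial, velocity_threshold_dps = 30,
                               min_duration_ms = 60, chin_offset_m = 0.12) {
  keep <- intersect(c("frame", "time_s", .sg_gaze_marker_cols()),
                    names(trial$markers))
  markers <- trial$markers[keep]
  attr(markers, "rate") <- attr(trial$markers, "rate")
  markers <- lowpass_filter(markers, 6)
  layout <- build_aoi_layout(markers, chin_offset_m)
  window <- support_period(markers, trial$meta$release_s)
  fix <- detect_fixations(trial$gaze, velocity_threshold_dps,
                          min_duration_ms)
  aoi_metrics(fix, layout, window)
}

#' Participant-level gaze metrics table
#'
#' Averages the per-trial AOI metrics within each participant, yielding the
#' participant x AOI table the group statistics run on. Latency and
#' per-visit means average over the trials where they exist.
#'
#' @param trial_metrics tibble from [run_cohort()]`$gaze` (one row per
#'   trial x AOI with `participant`, `group`).
#' @return tibble `participant`, `group`, `aoi`, four metric columns.
#' @export
participant_gaze_metrics <- function(trial_metrics) {
  dplyr::summarise(
    dplyr::group_by(trial_metrics, .data$participant, .data$group,
                    .data$aoi),
    total_duration_pct = mean(.data$total_duration_pct),
    n_fixations = mean(.data$n_fixations),
    mean_visit_ms = if (all(is.na(.data$mean_visit_ms))) NA_real_ else
      mean(.data$mean_visit_ms, na.rm = TRUE),
    latency_ms = if (all(is.na(.data$latency_ms))) NA_real_ else
      mean(.data$latency_ms, na.rm = TRUE),
    .groups = "drop")
}


# Marker columns needed by the gaze pipeline (trunk frame + AOI landmarks).
.sg_gaze_marker_cols <- function() {
  m <- c("CLAV", "STRN", "T2", "T7", "LFHD", "RFHD", "LBHD", "RBHD",
         "LSHO", "RSHO", "LHIP", "RHIP", "LKNE", "RKNE", "LANK", "RANK",
         "LHEE", "RHEE", "LTOE", "RTOE")
  paste0(rep(m, each = 3), "_", c("x", "y", "z"))
}
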