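#' Motion script for one assisted stand/sit trial
#'
#' A trial consists of `cycles` consecutive stand-up/sit-down cycles. Each
#' cycle runs through a fixed phase sequence (seated pause, forward lean,
#' hold with seat-off, rise, stand, sit) whose durations are configurable.
#' The three scripted per-trial indices are the quantities the analysis
#' pipeline is expected to recover: the deepest forward trunk-flexion angle,
#' the mean forward COM velocity between seat-off and maximum ankle
#' dorsiflexion, and the signed forward COM-to-heel distance at seat-off
#' (negative = COM behind the trailing edge of the base of support).
#'
#' @param peak_flexion_deg deepest forward trunk flexion reached during each
#'   lean (degrees, >= 0).
#' @param com_velocity_ms mean forward COM velocity over the seat-off to
#'   maximum-dorsiflexion window (m/s, >= 0).
#' @param com_bos_m signed forward distance COM minus rearmost heel marker at
#'   seat-off (m); negative when the COM is behind the heel line.
#' @param cycles number of stand/sit cycles (default 5).
#' @param lead_s,seated_s,lean_s,hold_s,rise_s,stand_s,sit_s,tail_s phase
#'   durations in seconds. Seat-off occurs at the midpoint of the hold phase,
#'   after peak flexion has been reached.
#' @param dorsi_peak_after_s time from seat-off to the scripted maximum ankle
#'   dorsiflexion; must fall inside the rise phase.
#' @param release_after_s hand-release margin after the final rise completes;
#'   defines the end of the gaze support period.
#' @param grf_decay_s duration of the smooth rear-plate unloading that ends
#'   exactly at seat-off (and of the reload at the end of each sit-down).
#' @param grf_seated_frac fraction of body weight on the chair when seated.
#' @param seatoff_ref_n rear-plate force level (N) at which the scripted
#'   indices are anchored; matches the event detector's default threshold so
#'   the round trip is unbiased.
#' @return object of class `sg_motion_script`.
#' @export
#' @examples
#' script <- motion_script(peak_flexion_deg = 41)
#' script$seat_off_s
motion_script <- function(peak_flexion_deg = 39,
                          com_velocity_ms = 0.46,
                          com_bos_m = -0.035,
                          cycles = 5,
                          lead_s = 1.0, seated_s = 0.6, lean_s = 1.2,
                          hold_s = 0.3, rise_s = 1.0, stand_s = 0.8,
                          sit_s = 1.3, tail_s = 1.0,
                          dorsi_peak_after_s = 0.4,
                          release_after_s = 0.3,
                          grf_decay_s = 0.4, grf_seated_frac = 0.75,
                          seatoff_ref_n = 5) {
  durs <- c(lead_s = lead_s, seated_s = seated_s, lean_s = lean_s,
            hold_s = hold_s, rise_s = rise_s, stand_s = stand_s,
            sit_s = sit_s, tail_s = tail_s)
  abort_if(any(!is.finite(durs)) || any(durs <= 0),
           "all phase durations must be positive and finite",
           class = "standgaze_validation_error")
  abort_if(!is.numeric(cycles) || cycles < 1 || cycles != round(cycles),
           "cycles must be a positive integer",
           class = "standgaze_validation_error")
  abort_if(!is.finite(peak_flexion_deg) || peak_flexion_deg < 0 ||
             peak_flexion_deg > 90,
           "peak trunk flexion must lie in [0, 90] degrees",
           class = "standgaze_validation_error")
  abort_if(!is.finite(com_velocity_ms) || com_velocity_ms < 0,
           "COM velocity must be >= 0 m/s",
           class = "standgaze_validation_error")
  abort_if(!is.finite(com_bos_m),
           "COM-BOS distance must be finite",
           class = "standgaze_validation_error")
  abort_if(dorsi_peak_after_s <= 0 || dorsi_peak_after_s >= hold_s / 2 + rise_s,
           "maximum dorsiflexion must occur inside the rise, after seat-off",
           class = "standgaze_validation_error")
  abort_if(grf_decay_s <= 0 || grf_decay_s > lean_s + hold_s / 2,
           "force unloading must fit inside the lean/hold phases",
           class = "standgaze_validation_error")
  abort_if(grf_seated_frac <= 0 || grf_seated_frac >= 1,
           "seated weight fraction must lie in (0, 1)",
           class = "standgaze_validation_error")

  cycle_len <- seated_s + lean_s + hold_s + rise_s + stand_s + sit_s
  cycle_start <- lead_s + (seq_len(cycles) - 1) * cycle_len
  lean_on <- cycle_start + seated_s
  seat_off <- lean_on + lean_s + hold_s / 2
  rise_end <- lean_on + lean_s + hold_s + rise_s
  sit_start <- rise_end + stand_s
  sit_end <- sit_start + sit_s

  structure(list(
    peak_flexion_deg = peak_flexion_deg,
    com_velocity_ms = com_velocity_ms,
    com_bos_m = com_bos_m,
    cycles = as.integer(cycles),
    lead_s = lead_s, seated_s = seated_s, lean_s = lean_s, hold_s = hold_s,
    rise_s = rise_s, stand_s = stand_s, sit_s = sit_s, tail_s = tail_s,
    dorsi_peak_after_s = dorsi_peak_after_s,
    release_after_s = release_after_s,
    grf_decay_s = grf_decay_s, grf_seated_frac = grf_seated_frac,
    seatoff_ref_n = seatoff_ref_n,
    cycle_len_s = cycle_len,
    cycle_start_s = cycle_start,
    lean_onset_s = lean_on,
    seat_off_s = seat_off,
    dorsi_peak_s = seat_off + dorsi_peak_after_s,
    rise_end_s = rise_end,
    sit_start_s = sit_start,
    sit_end_s = sit_end,
    release_s = rise_end[cycles] + release_after_s,
    duration_s = sit_end[cycles] + tail_s
  ), class = "sg_motion_script")
}

#' @export
print.sg_motion_script <- function(x, ...) {
  cat(sprintf(
    "<sg_motion_script> %d cycles, %.1f s; peak flexion %.1f deg, COM velocity %.3f m/s, COM-BOS %+.3f m\n",
    x$cycles, x$duration_s, x$peak_flexion_deg, x$com_velocity_ms, x$com_bos_m))
  invisible(x)
}

validate_script <- function(script) {
  abort_if(!inherits(script, "sg_motion_script"),
           "`script` must be created by motion_script()",
           class = "standgaze_validation_error")
  invisible(script)
}
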