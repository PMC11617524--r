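# I-VT fixation detection: velocity-threshold identification.

#' Detect fixations with an I-VT filter
#'
#' Classifies each gaze sample by its point-to-point angular velocity
#' (displacement in the analysis plane divided by the viewing distance and
#' the sample interval). Consecutive samples below `velocity_threshold_dps`
#' are merged into fixation candidates; candidates shorter than
#' `min_duration_ms` are discarded. Invalid samples break fixations. A
#' stream shorter than the minimum duration yields an empty sequence, not an
#' error.
#'
#' @param gaze tibble with `time_ms`, `x`, `y` (metres in the analysis
#'   plane) and optional `validity` (1 = valid).
#' @param velocity_threshold_dps I-VT velocity threshold in degrees/second
#'   (default 30, the common vendor default).
#' @param min_duration_ms minimum fixation duration in ms (default 60).
#' @param viewing_distance_m assumed eye-to-plane distance used to convert
#'   planar displacement to visual angle (default 1).
#' @return tibble of class `sg_fixations`: `fixation`, `start_ms`,
#'   `duration_ms`, `x`, `y` (centroid), time-ordered and non-overlapping.
#' @export
#' @examples
#' g <- tibble::tibble(time_ms = seq(0, 480, 20), x = 0, y = 1)
#' detect_fixations(g)
detect_fixations <- function(gaze, velocity_threshold_dps = 30,
                             min_duration_ms = 60,
                             viewing_distance_m = 1) {
  abort_if(!all(c("time_ms", "x", "y") %in% names(gaze)),
           "gaze needs columns time_ms, x, y")
  n <- nrow(gaze)
  empty <- tibble::tibble(fixation = integer(), start_ms = numeric(),
                          duration_ms = numeric(), x = numeric(),
                          y = numeric())
  class(empty) <- c("sg_fixations", class(empty))
  if (n < 2) return(empty)
  abort_if(is.unsorted(gaze$time_ms, strictly = TRUE),
           "gaze timestamps must be strictly increasing",
           class = "standgaze_validation_error")
  valid <- if ("validity" %in% names(gaze)) gaze$validity >= 1 else rep(TRUE, n)
  valid <- valid & !is.na(gaze$x) & !is.na(gaze$y)

  dt <- diff(gaze$time_ms) / 1000
  disp <- sqrt(diff(gaze$x)^2 + diff(gaze$y)^2)
  vel <- atan2(disp, viewing_distance_m) * 180 / pi / dt
  # per-sample velocity: backward difference; first sample inherits the second
  v_s <- c(vel[1], vel)
  is_fix <- v_s <= velocity_threshold_dps & valid

  r <- rle(is_fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) return(empty)
  s <- starts[keep]
  e <- ends[keep]
  cx <- cumsum(c(0, gaze$x))
  cy <- cumsum(c(0, gaze$y))
  len <- e - s + 1
  fix <- tibble::tibble(
    start_ms = gaze$time_ms[s],
    duration_ms = gaze$time_ms[e] - gaze$time_ms[s],
    x = (cx[e + 1] - cx[s]) / len,
    y = (cy[e + 1] - cy[s]) / len)
  fix <- fix[fix$duration_ms >= min_duration_ms, ]
  fix <- tibble::add_column(fix, fixation = seq_len(nrow(fix)), .before = 1)
  class(fix) <- c("sg_fixations", class(fix))
  fix
}
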