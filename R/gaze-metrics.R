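# The four AOI gaze metrics over the support period.

#' Support period of a trial
#'
#' The analysis window runs from the onset of the collaborator's first
#' stand-up motion -- the first time the trunk angular velocity exceeds
#' `threshold_dps` -- to the scripted hand-release time after the final
#' stand-up.
#'
#' @param markers (filtered) marker tibble of the trial.
#' @param release_s hand-release time in seconds (from the trial metadata).
#' @param threshold_dps trunk angular-velocity onset threshold (default 5).
#' @return numeric `c(start_s, end_s)`.
#' @export
support_period <- function(markers, release_s, threshold_dps = 5) {
  ang <- trunk_angle(markers)
  t <- ang$time_s
  abort_if(release_s > max(t) + 1e-9 || release_s < min(t),
           "release time lies outside the recording",
           class = "standgaze_validation_error")
  omega <- c(0, diff(ang$angle_deg) / diff(t))
  idx <- which(abs(omega) > threshold_dps)
  abort_if(length(idx) == 0,
           "no stand-up onset found (trunk never moves above threshold)",
           class = "standgaze_event_error")
  onset <- t[idx[1]]
  abort_if(onset >= release_s, "onset found after the release time",
           class = "standgaze_validation_error")
  c(start_s = onset, end_s = release_s)
}

# Label fixations by the AOI band containing their centroid at the fixation
# midpoint, clip them to the window, and drop fixations entirely outside it.
.sg_labelled_fixations <- function(fixations, layout, window) {
  if (nrow(fixations) == 0) {
    return(tibble::tibble(fixation = integer(), start_ms = numeric(),
                          duration_ms = numeric(), overlap_ms = numeric(),
                          aoi = character()))
  }
  w0 <- window[1] * 1000
  w1 <- window[2] * 1000
  end_ms <- fixations$start_ms + fixations$duration_ms
  overlap <- pmax(0, pmin(end_ms, w1) - pmax(fixations$start_ms, w0))
  mid_s <- (fixations$start_ms + fixations$duration_ms / 2) / 1000
  lab <- classify_aoi(layout, mid_s, fixations$y)
  out <- tibble::tibble(fixation = fixations$fixation,
                        start_ms = fixations$start_ms,
                        duration_ms = fixations$duration_ms,
                        overlap_ms = overlap, aoi = lab)
  out[out$overlap_ms > 0, ]
}

# Internal metric cores operating on one labelled-fixation table, so the
# combined aoi_metrics() labels fixations only once.
.sg_metric_dwell <- function(lf, W_ms) {
  base <- tibble::tibble(aoi = aoi_names(), total_duration_pct = 0)
  if (nrow(lf) == 0) return(base)
  agg <- dplyr::summarise(
    dplyr::group_by(lf[!is.na(lf$aoi), ], .data$aoi),
    dur = sum(.data$overlap_ms), .groups = "drop")
  base$total_duration_pct <- agg$dur[match(base$aoi, agg$aoi)] / W_ms * 100
  base$total_duration_pct[is.na(base$total_duration_pct)] <- 0
  base
}

.sg_metric_count <- function(lf) {
  base <- tibble::tibble(aoi = aoi_names(), n_fixations = 0L)
  if (nrow(lf) == 0) return(base)
  agg <- dplyr::count(lf[!is.na(lf$aoi), ], .data$aoi)
  base$n_fixations <- agg$n[match(base$aoi, agg$aoi)]
  base$n_fixations[is.na(base$n_fixations)] <- 0L
  base
}

.sg_metric_visits <- function(lf) {
  base <- tibble::tibble(aoi = aoi_names(), mean_visit_ms = NA_real_,
                         n_visits = 0L)
  if (nrow(lf) == 0) return(base)
  lf <- lf[order(lf$start_ms), ]
  lab <- ifelse(is.na(lf$aoi), "__off__", lf$aoi)
  run <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
  visits <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(aoi = lab, run = run,
                                   dur = lf$overlap_ms),
                    .data$aoi, .data$run),
    dur = sum(.data$dur), .groups = "drop")
  visits <- visits[visits$aoi != "__off__", ]
  if (nrow(visits) == 0) return(base)
  agg <- dplyr::summarise(dplyr::group_by(visits, .data$aoi),
                          mean_visit_ms = mean(.data$dur),
                          n_visits = dplyr::n(), .groups = "drop")
  i <- match(base$aoi, agg$aoi)
  base$mean_visit_ms <- agg$mean_visit_ms[i]
  base$n_visits <- ifelse(is.na(i), 0L, agg$n_visits[i])
  base
}

.sg_metric_latency <- function(lf, w0_ms) {
  base <- tibble::tibble(aoi = aoi_names(), latency_ms = NA_real_)
  lf <- lf[!is.na(lf$aoi), ]
  if (nrow(lf) == 0) return(base)
  agg <- dplyr::summarise(
    dplyr::group_by(lf, .data$aoi),
    latency_ms = min(pmax(.data$start_ms, w0_ms)) - w0_ms,
    .groups = "drop")
  base$latency_ms <- agg$latency_ms[match(base$aoi, agg$aoi)]
  base
}

#' Total duration of fixation per AOI
#'
#' Summed fixation time inside each AOI divided by the support-period
#' length, as a percentage.
#'
#' @param fixations an [detect_fixations()] result.
#' @param layout an [build_aoi_layout()] result.
#' @param window `c(start_s, end_s)` support period.
#' @return tibble `aoi`, `total_duration_pct` (all six AOIs, zeros included).
#' @export
total_duration_pct <- function(fixations, layout, window) {
  .sg_metric_dwell(.sg_labelled_fixations(fixations, layout, window),
                   diff(window) * 1000)
}

#' Number of fixations per AOI
#'
#' @inheritParams total_duration_pct
#' @return tibble `aoi`, `n_fixations`.
#' @export
n_fixations <- function(fixations, layout, window) {
  .sg_metric_count(.sg_labelled_fixations(fixations, layout, window))
}

#' Mean fixation time per visit, per AOI
#'
#' A visit is a maximal run of consecutive fixations on one AOI, ended by
#' the next fixation outside it (including off-AOI fixations). The visit
#' duration is the sum of its fixation durations; the metric is the mean
#' over visits. AOIs with no visits get `NA`.
#'
#' @inheritParams total_duration_pct
#' @return tibble `aoi`, `mean_visit_ms`, `n_visits`.
#' @export
mean_fixation_per_visit <- function(fixations, layout, window) {
  .sg_metric_visits(.sg_labelled_fixations(fixations, layout, window))
}

#' Latency to first fixation per AOI
#'
#' Time from the window start to the onset of the first fixation on each
#' AOI, in milliseconds; `NA` when the AOI is never fixated (excluded from
#' group averages downstream).
#'
#' @inheritParams total_duration_pct
#' @return tibble `aoi`, `latency_ms`.
#' @export
latency_first_fixation <- function(fixations, layout, window) {
  .sg_metric_latency(.sg_labelled_fixations(fixations, layout, window),
                     window[1] * 1000)
}

#' All four AOI gaze metrics for one trial
#'
#' @inheritParams total_duration_pct
#' @return tibble `aoi` x (`total_duration_pct`, `n_fixations`,
#'   `mean_visit_ms`, `latency_ms`).
#' @export
aoi_metrics <- function(fixations, layout, window) {
  lf <- .sg_labelled_fixations(fixations, layout, window)
  out <- .sg_metric_dwell(lf, diff(window) * 1000)
  out$n_fixations <- .sg_metric_count(lf)$n_fixations
  out$mean_visit_ms <- .sg_metric_visits(lf)$mean_visit_ms
  out$latency_ms <- .sg_metric_latency(lf, window[1] * 1000)$latency_ms
  out
}
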