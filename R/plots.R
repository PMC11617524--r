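# ggplot2 displays for the main result types.

#' Plot group gaze metrics by AOI
#'
#' Bar chart of the group mean (+/- sd) of one gaze metric per AOI,
#' experts and novices side by side.
#'
#' @param metrics participant-level gaze metrics table.
#' @param metric which metric column to plot.
#' @return a ggplot object.
#' @export
plot_gaze_metrics <- function(metrics, metric = "total_duration_pct") {
  gsum <- summarise_gaze_metrics(metrics)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  gsum$aoi <- factor(gsum$aoi, levels = aoi_names())
  ggplot2::ggplot(gsum, ggplot2::aes(
    x = .data$aoi, y = .data[[mcol]], fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data[[mcol]] - .data[[scol]], 0),
                   ymax = .data[[mcol]] + .data[[scol]]),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = "Area of interest", y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot trial-level kinematic indices by group
#'
#' Boxplots of the three per-trial indices, one facet each.
#'
#' @param indices trial-level kinematic tibble.
#' @return a ggplot object.
#' @export
plot_kinematics <- function(indices) {
  long <- tidyr::pivot_longer(
    indices[c("group", "deepest_trunk_deg", "com_bos_m",
              "com_velocity_ms")],
    -"group", names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the COM trajectory of one trial
#'
#' Forward COM position over time with seat-off and maximum-dorsiflexion
#' events marked.
#'
#' @param trial an `sg_trial`.
#' @param ... passed to [trial_kinematics()].
#' @return a ggplot object.
#' @export
autoplot.sg_trial <- function(trial, ...) {
  kin <- trial_kinematics(trial, ...)
  markers <- lowpass_filter(interpolate_gaps(trial$markers), 6)
  pose <- calibrate_virtual_asis(.sg_first_complete_frame(markers))
  markers <- reconstruct_asis(markers, pose)
  com <- whole_body_com(markers)
  ggplot2::ggplot(com, ggplot2::aes(.data$time_s, .data$com_y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = kin$cycles$seat_off_s,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = kin$cycles$t_max_dorsi_s,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "forward COM position (m)",
                  subtitle = "dashed: seat-off, dotted: max dorsiflexion") +
    ggplot2::theme_minimal()
}
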