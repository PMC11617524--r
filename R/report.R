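# Tabular reports: the machine twins of the published gaze-metrics and
# kinematic-indices tables.

#' Group summary of the gaze metrics table
#'
#' Mean (sd) of each of the four AOI metrics per group and AOI.
#'
#' @param metrics participant-level table ([participant_gaze_metrics()]).
#' @return tibble `group`, `aoi`, metric mean/sd columns.
#' @export
summarise_gaze_metrics <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(metrics, .data$group, .data$aoi),
    dplyr::across(
      dplyr::all_of(c("total_duration_pct", "n_fixations",
                      "mean_visit_ms", "latency_ms")),
      list(mean = ~ mean(.x, na.rm = TRUE),
           sd = ~ stats::sd(.x, na.rm = TRUE))),
    n = dplyr::n(), .groups = "drop")
}

#' Group summary of the kinematic indices
#'
#' Range, mean (sd) and median (Q1-Q3) of each trial-level index per group,
#' in the layout of the published kinematics table.
#'
#' @param indices trial-level tibble ([run_cohort()]`$kinematics`).
#' @return tibble `index`, `group`, `min`, `max`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `n_trials`.
#' @export
summarise_kinematics <- function(indices) {
  long <- tidyr::pivot_longer(
    indices[c("group", "deepest_trunk_deg", "com_bos_m",
              "com_velocity_ms")],
    -"group", names_to = "index", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$index, .data$group),
    min = min(.data$value), max = max(.data$value),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    median = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25)[[1]],
    q3 = stats::quantile(.data$value, 0.75)[[1]],
    n_trials = dplyr::n(), .groups = "drop")
}

#' Render the cohort report
#'
#' Writes `gaze_metrics.csv` (participant x AOI), `kinematics.csv` (one row
#' per trial), their group summaries (`table_gaze.csv`,
#' `table_kinematics.csv`), optional statistics, and a human-readable
#' `summary.txt`.
#'
#' @param metrics participant-level gaze metrics table.
#' @param indices trial-level kinematic indices.
#' @param path output directory.
#' @param stats optional list of fitted objects (`sg_mixed_anova`,
#'   `sg_group_comparison`) to include in the summary.
#' @return invisibly, a named list of the files written.
#' @export
render_report <- function(metrics, indices, path, stats = list()) {
  abort_if(nrow(metrics) == 0 || nrow(indices) == 0,
           "empty cohort: nothing to report",
           class = "standgaze_validation_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    gaze_metrics = file.path(path, "gaze_metrics.csv"),
    kinematics = file.path(path, "kinematics.csv"),
    table_gaze = file.path(path, "table_gaze.csv"),
    table_kinematics = file.path(path, "table_kinematics.csv"),
    summary = file.path(path, "summary.txt"))
  readr::write_csv(metrics, files["gaze_metrics"], na = "")
  readr::write_csv(indices, files["kinematics"], na = "")
  gsum <- summarise_gaze_metrics(metrics)
  ksum <- summarise_kinematics(indices)
  readr::write_csv(gsum, files["table_gaze"], na = "")
  readr::write_csv(ksum, files["table_kinematics"], na = "")

  con <- file(files["summary"], "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("Assisted sit-to-stand cohort report")
  wl("===================================")
  wl("")
  wl("Gaze: total duration of fixation to AOI, %% of support period")
  for (g in unique(gsum$group)) {
    wl("  %s:", g)
    sub <- gsum[gsum$group == g, ]
    sub <- sub[match(aoi_names(), sub$aoi), ]
    for (i in seq_len(nrow(sub))) {
      wl("    %-6s %6.2f (%.2f)   fixations %6.2f (%.2f)", sub$aoi[i],
         sub$total_duration_pct_mean[i], sub$total_duration_pct_sd[i],
         sub$n_fixations_mean[i], sub$n_fixations_sd[i])
    }
  }
  wl("")
  wl("Kinematic indices (per trial, mean over cycles)")
  for (i in seq_len(nrow(ksum))) {
    wl("  %-18s %-7s Range %8.3f to %8.3f  Mean (SD) %8.3f (%.3f)  Median (Q1-Q3) %8.3f (%.3f to %.3f)",
       ksum$index[i], ksum$group[i], ksum$min[i], ksum$max[i],
       ksum$mean[i], ksum$sd[i], ksum$median[i], ksum$q1[i], ksum$q3[i])
  }
  if (length(stats) > 0) {
    wl("")
    wl("Statistics")
    for (s in stats) {
      txt <- utils::capture.output(print(s))
      writeLines(paste0("  ", txt), con)
    }
  }
  invisible(as.list(files))
}
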