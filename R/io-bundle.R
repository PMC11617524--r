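# Canonical trial bundle: markers.csv + grf.csv + gaze.tsv + meta.yaml.
# UTF-8, '.' decimal separator, RFC-4180 quoting; missing data are empty
# fields, never sentinel zeros. All internal computation is in SI units
# (m, s, N); conversions happen only here.

#' Write a trial bundle
#'
#' Writes `markers.csv` (frame, time_s, 37 markers x X/Y/Z in metres),
#' `grf.csv` (time_s, plate_id, Fx, Fy, Fz in newtons), `gaze.tsv`
#' (timestamp_ms, gaze_x, gaze_y, validity; tab-delimited in the vendor
#' style) and `meta.yaml` into `path`.
#'
#' @param trial an `sg_trial`.
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trial_bundle <- function(trial, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$markers, file.path(path, "markers.csv"), na = "")
  grf <- dplyr::rename(trial$grf, plate_id = "plate",
                       Fx = "fx", Fy = "fy", Fz = "fz")
  readr::write_csv(grf, file.path(path, "grf.csv"), na = "")
  gaze <- dplyr::rename(trial$gaze, timestamp_ms = "time_ms",
                        gaze_x = "x", gaze_y = "y")
  readr::write_tsv(gaze, file.path(path, "gaze.tsv"), na = "")
  yaml::write_yaml(trial$meta, file.path(path, "meta.yaml"))
  invisible(path)
}

.sg_parse_error <- function(file, msg) {
  rlang::abort(sprintf("%s: %s", file, msg),
               class = "standgaze_parse_error")
}

#' Read a trial bundle
#'
#' Reads the canonical bundle written by [write_trial_bundle()], validating
#' units (positions in millimetres are converted to metres when
#' `meta.yaml` declares `units: markers: mm`), monotone gaze timestamps and
#' duplicate-free time bases. Missing marker samples stay missing.
#'
#' @param path bundle directory.
#' @return an `sg_trial`.
#' @export
read_trial_bundle <- function(path) {
  need <- c("markers.csv", "grf.csv", "gaze.tsv", "meta.yaml")
  missing_f <- need[!file.exists(file.path(path, need))]
  abort_if(length(missing_f) > 0,
           paste("bundle is missing:", paste(missing_f, collapse = ", ")),
           class = "standgaze_parse_error")
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))

  mfile <- file.path(path, "markers.csv")
  markers <- readr::read_csv(mfile, show_col_types = FALSE, progress = FALSE)
  abort_if(!all(c("frame", "time_s") %in% names(markers)),
           paste0(mfile, ": needs frame and time_s columns"),
           class = "standgaze_parse_error")
  dup <- which(duplicated(markers$time_s))
  if (length(dup) > 0) {
    .sg_parse_error(mfile, sprintf("duplicate timestamp at line %d",
                                   dup[1] + 1L))
  }
  unit <- meta$units$markers %||% "m"
  if (identical(unit, "mm")) {
    cols <- grep("_(x|y|z)$", names(markers), value = TRUE)
    markers[cols] <- markers[cols] / 1000
    meta$units$markers <- "m"
  } else if (!identical(unit, "m")) {
    .sg_parse_error(file.path(path, "meta.yaml"),
                    sprintf("unsupported marker unit '%s'", unit))
  }
  attr(markers, "rate") <- meta$rates$markers %||%
    (1 / stats::median(diff(markers$time_s)))

  gfile <- file.path(path, "grf.csv")
  grf <- readr::read_csv(gfile, show_col_types = FALSE, progress = FALSE)
  abort_if(!all(c("time_s", "plate_id", "Fx", "Fy", "Fz") %in% names(grf)),
           paste0(gfile, ": needs time_s, plate_id, Fx, Fy, Fz"),
           class = "standgaze_parse_error")
  grf <- dplyr::rename(grf, plate = "plate_id", fx = "Fx", fy = "Fy",
                       fz = "Fz")
  for (pl in unique(grf$plate)) {
    tp <- grf$time_s[grf$plate == pl]
    bad <- which(diff(tp) <= 0)
    if (length(bad) > 0) {
      .sg_parse_error(gfile, sprintf(
        "non-increasing timestamps for plate %s near entry %d", pl, bad[1]))
    }
  }
  attr(grf, "rate") <- meta$rates$grf %||% NULL
  attr(grf, "rear_plates") <- unlist(meta$rear_plates) %||% c(5L, 6L)

  zfile <- file.path(path, "gaze.tsv")
  gaze <- readr::read_tsv(zfile, show_col_types = FALSE, progress = FALSE)
  abort_if(!all(c("timestamp_ms", "gaze_x", "gaze_y") %in% names(gaze)),
           paste0(zfile, ": needs timestamp_ms, gaze_x, gaze_y"),
           class = "standgaze_parse_error")
  bad <- which(diff(gaze$timestamp_ms) <= 0)
  if (length(bad) > 0) {
    .sg_parse_error(zfile, sprintf(
      "gaze timestamps not strictly increasing at line %d", bad[1] + 2L))
  }
  gaze <- dplyr::rename(gaze, time_ms = "timestamp_ms", x = "gaze_x",
                        y = "gaze_y")
  if (!"validity" %in% names(gaze)) gaze$validity <- 1L

  structure(list(markers = markers, grf = grf, gaze = gaze, meta = meta),
            class = "sg_trial")
}
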