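# Virtual ASIS reconstruction from the rigid sacral jig cluster.

# Orthonormal local frame of the three jig markers for every row of a wide
# marker matrix/tibble. Returns list(origin = n x 3, R = list of per-frame
# 3 x 3) -- vectorised as three n x 3 basis matrices.
.sg_jig_frame <- function(M) {
  get3 <- function(name) cbind(M[[paste0(name, "_x")]],
                               M[[paste0(name, "_y")]],
                               M[[paste0(name, "_z")]])
  p1 <- get3("SJ1"); p2 <- get3("SJ2"); p3 <- get3("SJ3")
  e1 <- p2 - p1
  n1 <- sqrt(rowSums(e1^2))
  abort_if(any(n1 < 1e-9, na.rm = TRUE), "coincident jig markers")
  e1 <- e1 / n1
  v <- p3 - p1
  e3 <- cross3_rows(e1, v)
  n3 <- sqrt(rowSums(e3^2))
  abort_if(any(n3 < 1e-6 * sqrt(rowSums(v^2)), na.rm = TRUE),
           "collinear jig markers: cannot build a pelvis frame",
           class = "standgaze_validation_error")
  e3 <- e3 / n3
  e2 <- cross3_rows(e3, e1)
  list(origin = p1, e1 = e1, e2 = e2, e3 = e3)
}

#' Calibrate virtual ASIS offsets from a static frame
#'
#' Measures the left and right ASIS positions in the orthonormal local frame
#' built from the three sacral-jig markers during a static pose in which all
#' pelvis markers are visible. The stored offsets later reconstruct the ASIS
#' whenever the jig is visible, regardless of pelvis pose (rigid-body
#' assumption).
#'
#' @param static_frame a one-row slice of a marker tibble (or a named list /
#'   one-row data frame) with all jig and ASIS markers present.
#' @return object of class `sg_calibration`: local-frame offset vectors for
#'   `LASI` and `RASI`.
#' @export
calibrate_virtual_asis <- function(static_frame) {
  f <- tibble::as_tibble(as.list(static_frame)[
    grep("_(x|y|z)$", names(static_frame), value = TRUE)])
  need <- paste0(rep(c("SJ1", "SJ2", "SJ3", "LASI", "RASI"), each = 3),
                 "_", c("x", "y", "z"))
  abort_if(!all(need %in% names(f)) || anyNA(f[need]),
           "static frame must contain visible jig and ASIS markers",
           class = "standgaze_validation_error")
  jf <- .sg_jig_frame(f)
  local_of <- function(name) {
    p <- c(f[[paste0(name, "_x")]], f[[paste0(name, "_y")]],
           f[[paste0(name, "_z")]])
    d <- p - as.numeric(jf$origin)
    c(sum(d * jf$e1), sum(d * jf$e2), sum(d * jf$e3))
  }
  structure(list(LASI = local_of("LASI"), RASI = local_of("RASI")),
            class = "sg_calibration")
}

#' @export
print.sg_calibration <- function(x, ...) {
  cat("<sg_calibration> jig-frame ASIS offsets (m):\n")
  cat(sprintf("  LASI %s\n  RASI %s\n",
              paste(sprintf("%+.4f", x$LASI), collapse = " "),
              paste(sprintf("%+.4f", x$RASI), collapse = " ")))
  invisible(x)
}

#' Reconstruct occluded ASIS markers from the sacral jig
#'
#' Replaces missing ASIS samples with virtual markers computed from the jig
#' cluster and the calibrated offsets. Where the real ASIS is visible it is
#' kept, and the discrepancy between measured and virtual position is
#' reported as a quality metric. Frames with an occluded jig are flagged
#' unrecoverable (left missing).
#'
#' @param markers marker tibble.
#' @param pose an [calibrate_virtual_asis()] result.
#' @return the marker tibble with ASIS gaps filled; attributes
#'   `asis_quality` (RMS measured-vs-virtual discrepancy in metres over
#'   frames where both exist) and `asis_unrecoverable` (count of frames with
#'   both ASIS and jig missing).
#' @export
reconstruct_asis <- function(markers, pose) {
  abort_if(!inherits(pose, "sg_calibration"),
           "`pose` must come from calibrate_virtual_asis()")
  jig_ok <- !is.na(markers$SJ1_x) & !is.na(markers$SJ2_x) &
    !is.na(markers$SJ3_x)
  out <- markers
  quality <- c()
  unrec <- 0L
  sub <- markers[jig_ok, , drop = FALSE]
  if (nrow(sub) > 0) {
    jf <- .sg_jig_frame(sub)
    for (name in c("LASI", "RASI")) {
      off <- pose[[name]]
      virt <- jf$origin + off[1] * jf$e1 + off[2] * jf$e2 + off[3] * jf$e3
      cx <- paste0(name, "_x"); cy <- paste0(name, "_y")
      cz <- paste0(name, "_z")
      meas <- cbind(sub[[cx]], sub[[cy]], sub[[cz]])
      vis <- !is.na(meas[, 1])
      if (any(vis)) {
        quality <- c(quality, rowSums((meas[vis, , drop = FALSE] -
                                         virt[vis, , drop = FALSE])^2))
      }
      fill <- which(jig_ok)[!vis]
      out[fill, cx] <- virt[!vis, 1]
      out[fill, cy] <- virt[!vis, 2]
      out[fill, cz] <- virt[!vis, 3]
    }
  }
  unrec <- sum(!jig_ok & is.na(markers$LASI_x))
  for (a in c("rate", "events", "script")) attr(out, a) <- attr(markers, a)
  attr(out, "asis_quality") <- if (length(quality)) sqrt(mean(quality)) else NA_real_
  attr(out, "asis_unrecoverable") <- unrec
  out
}
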