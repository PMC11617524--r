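# Synchronisation, zero-phase smoothing and marker gap interpolation.

# Zero-phase Butterworth low-pass on a numeric vector. Forward-backward pass
# with odd (point-reflected) end padding so the response is zero-lag and the
# DC gain is exactly 1. NA runs are filtered piecewise (each contiguous valid
# run on its own); runs too short to pad are left untouched.
.sg_filtfilt <- function(x, cutoff_hz, rate_hz, order = 4) {
  ny <- rate_hz / 2
  abort_if(cutoff_hz <= 0 || cutoff_hz >= ny,
           sprintf("cutoff must lie in (0, %.4g) Hz (Nyquist)", ny),
           class = "standgaze_validation_error")
  bf <- signal::butter(order, cutoff_hz / ny, type = "low")
  b <- bf$b
  a <- bf$a

  # one IIR pass via C-level stats::filter: y = conv(x, b) fed through the
  # recursive part (a, normalised)
  iir <- function(x) {
    v <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                       sides = 1)
    v <- v[-seq_len(length(b) - 1)]
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }

  filter_run <- function(v) {
    n <- length(v)
    if (all(v == v[1])) return(v)  # constant: DC gain is exactly 1
    pad <- min(n - 1, max(3 * (order + 1), ceiling(3 * rate_hz / cutoff_hz)))
    if (pad < 3) return(v)
    xp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    yf <- iir(xp)
    yb <- rev(iir(rev(yf)))
    yb[(pad + 1):(pad + n)]
  }

  if (!anyNA(x)) return(filter_run(x))
  out <- x
  r <- rle(!is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] > 3 * (order + 1)) {
      idx <- starts[i]:ends[i]
      out[idx] <- filter_run(x[idx])
    }
  }
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order (by default) Butterworth filter applied forward and backward
#' (zero phase lag, squared magnitude response) with reflective end padding.
#' Operates on a numeric vector, a numeric matrix (column-wise), or a data
#' frame (all numeric columns except `frame`/`time_s`/`time_ms`/`plate`).
#' Missing runs are preserved: each contiguous valid run is filtered on its
#' own.
#'
#' @param x numeric vector, matrix, or data frame.
#' @param cutoff_hz filter cutoff in Hz; must be below the Nyquist frequency.
#' @param rate_hz sampling rate in Hz; for data frames defaults to the
#'   `rate` attribute if present.
#' @param order filter order per pass (default 4, the biomechanics norm).
#' @return object of the same shape as `x`, filtered.
#' @export
#' @examples
#' lowpass_filter(rep(1, 100), cutoff_hz = 6, rate_hz = 100)[1:3]
lowpass_filter <- function(x, cutoff_hz, rate_hz = NULL, order = 4) {
  if (is.data.frame(x)) {
    rate_hz <- rate_hz %||% attr(x, "rate")
    abort_if(is.null(rate_hz), "supply rate_hz (no rate attribute found)")
    skip <- c("frame", "time_s", "time_ms", "plate", "cycle", "validity")
    cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], skip)
    if ("plate" %in% names(x)) {
      out <- dplyr::group_by(x, .data$plate)
      out <- dplyr::mutate(out, dplyr::across(
        dplyr::all_of(cols), ~ .sg_filtfilt(.x, cutoff_hz, rate_hz, order)))
      out <- dplyr::ungroup(out)
    } else {
      out <- dplyr::mutate(x, dplyr::across(
        dplyr::all_of(cols), ~ .sg_filtfilt(.x, cutoff_hz, rate_hz, order)))
    }
    for (a in c("rate", "events", "script", "rear_plates")) {
      attr(out, a) <- attr(x, a)
    }
    return(out)
  }
  abort_if(is.null(rate_hz), "supply rate_hz for vector/matrix input")
  if (is.matrix(x)) {
    return(apply(x, 2, .sg_filtfilt, cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz, order = order))
  }
  .sg_filtfilt(x, cutoff_hz, rate_hz, order)
}

#' Resample force-plate data onto the marker time base
#'
#' Anti-alias low-passes every force channel (zero-phase Butterworth at 80%
#' of the target Nyquist frequency) and then linearly interpolates onto the
#' marker timestamps, reproducing the standard downsampling of 1,000 Hz
#' plate data to the 100 Hz motion-capture clock (10 ms resolution).
#'
#' @param grf long force tibble (`time_s`, `plate`, `fx`, `fy`, `fz`) with a
#'   `rate` attribute (or pass `grf_rate`).
#' @param markers marker tibble with a `time_s` column (or a numeric vector
#'   of target timestamps).
#' @param grf_rate,marker_rate sampling rates in Hz; taken from attributes
#'   when absent.
#' @return force tibble on the marker time base, `rate` attribute updated.
#' @export
synchronize <- function(grf, markers, grf_rate = NULL, marker_rate = NULL) {
  grf_rate <- grf_rate %||% attr(grf, "rate")
  abort_if(is.null(grf_rate), "grf must carry a rate attribute or grf_rate")
  target_t <- if (is.numeric(markers)) markers else markers$time_s
  marker_rate <- marker_rate %||%
    (if (is.numeric(markers)) 1 / stats::median(diff(target_t))
     else attr(markers, "rate") %||% (1 / stats::median(diff(target_t))))
  abort_if(grf_rate < marker_rate,
           "force-plate rate must be >= the marker rate",
           class = "standgaze_validation_error")

  rng <- range(grf$time_s)
  abort_if(min(target_t) > rng[2] || max(target_t) < rng[1],
           "force-plate and marker time ranges do not overlap",
           class = "standgaze_validation_error")
  keep <- target_t >= rng[1] - 1e-9 & target_t <= rng[2] + 1e-9
  abort_if(!any(keep), "no marker timestamps fall inside the force recording",
           class = "standgaze_validation_error")
  tt <- target_t[keep]

  cutoff <- 0.8 * marker_rate / 2
  parts <- split(grf, grf$plate)
  out <- purrr::map_dfr(parts, function(df) {
    df <- df[order(df$time_s), ]
    res <- tibble::tibble(time_s = tt, plate = df$plate[1])
    for (ch in c("fx", "fy", "fz")) {
      v <- df[[ch]]
      if (cutoff < grf_rate / 2) v <- .sg_filtfilt(v, cutoff, grf_rate)
      res[[ch]] <- stats::approx(df$time_s, v, xout = tt)$y
    }
    res
  })
  out <- out[, c("time_s", "plate", "fx", "fy", "fz")]
  attr(out, "rate") <- marker_rate
  attr(out, "rear_plates") <- attr(grf, "rear_plates")
  out
}

#' Fill short marker gaps by cubic spline
#'
#' Missing runs no longer than `max_gap_s` (and bounded on both sides by
#' valid samples) are filled with a natural cubic spline through the valid
#' samples; longer runs and leading/trailing gaps are left missing and
#' reported in the `gap_report` attribute.
#'
#' @param markers marker tibble (`frame`, `time_s`, marker columns).
#' @param max_gap_s longest gap to fill, in seconds (default 0.2).
#' @param rate_hz sampling rate; defaults to the `rate` attribute.
#' @return the marker tibble with short gaps filled; attribute `gap_report`
#'   lists, per column, the number of samples filled and left missing.
#' @export
interpolate_gaps <- function(markers, max_gap_s = 0.2, rate_hz = NULL) {
  rate_hz <- rate_hz %||% attr(markers, "rate") %||%
    (1 / stats::median(diff(markers$time_s)))
  max_run <- max(1, floor(max_gap_s * rate_hz))
  cols <- setdiff(names(markers), c("frame", "time_s"))
  report <- list()
  out <- markers
  for (cl in cols) {
    v <- markers[[cl]]
    if (!anyNA(v)) next
    n_missing <- sum(is.na(v))
    if (all(is.na(v))) {
      report[[cl]] <- c(filled = 0L, left = n_missing)
      next
    }
    filled <- zoo::na.spline(v, x = markers$time_s, na.rm = FALSE,
                             maxgap = max_run)
    # never extrapolate into leading/trailing gaps
    valid <- which(!is.na(v))
    if (valid[1] > 1) filled[1:(valid[1] - 1)] <- NA_real_
    last <- valid[length(valid)]
    if (last < length(v)) filled[(last + 1):length(v)] <- NA_real_
    out[[cl]] <- filled
    report[[cl]] <- c(filled = n_missing - sum(is.na(filled)),
                      left = sum(is.na(filled)))
  }
  for (a in c("rate", "events", "script")) attr(out, a) <- attr(markers, a)
  attr(out, "gap_report") <- report
  out
}
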