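# Event detection: seat-off from rear-plate unloading, maximum ankle
# dorsiflexion, and per-cycle windows.

#' Detect seat-off events from rear force plates
#'
#' Seat-off is the instant the summed vertical force of the two plates under
#' the chair reaches 0 N. With sensor noise a literal zero never occurs, so
#' the detector finds the first downward crossing of a small threshold
#' `epsilon_n` that stays below it for at least `debounce_s`, and refines the
#' crossing time by linear interpolation between the bracketing samples
#' (`epsilon_n = 0` recovers the literal definition on clean data). The
#' force must re-arm (exceed `rearm_n`) between events, giving one event per
#' stand-up cycle.
#'
#' @param grf synchronized, filtered force tibble (`time_s`, `plate`, `fz`).
#' @param rear_plates plate ids under the chair; defaults to the
#'   `rear_plates` attribute, else `c(5, 6)`.
#' @param epsilon_n unloading threshold in newtons (default 5).
#' @param debounce_s time the force must stay below threshold (default 0.05).
#' @param rearm_n force level that re-arms the detector between cycles.
#' @param expected number of events expected (e.g. 5); if supplied and fewer
#'   are found, an error lists the cycles found.
#' @return tibble `cycle`, `seat_off_s`, `reload_s` (time the force re-arms
#'   after the event; `NA` for a final cycle that never reloads).
#' @export
detect_seat_off <- function(grf, rear_plates = NULL, epsilon_n = 5,
                            debounce_s = 0.05, rearm_n = 50,
                            expected = NULL) {
  rear_plates <- rear_plates %||% attr(grf, "rear_plates") %||% c(5L, 6L)
  sub <- grf[grf$plate %in% rear_plates, c("time_s", "plate", "fz")]
  abort_if(nrow(sub) == 0, "no rear-plate samples found")
  parts <- split(sub[c("time_s", "fz")], sub$plate)
  aligned <- length(unique(vapply(parts, nrow, integer(1)))) == 1 &&
    (length(parts) == 1 ||
       all(vapply(parts[-1], function(p) {
         isTRUE(all.equal(p$time_s, parts[[1]]$time_s))
       }, logical(1))))
  if (aligned) {
    ord <- order(parts[[1]]$time_s)
    t <- parts[[1]]$time_s[ord]
    f <- Reduce(`+`, lapply(parts, function(p) p$fz))[ord]
  } else {
    tot <- stats::aggregate(fz ~ time_s, data = sub, FUN = sum)
    tot <- tot[order(tot$time_s), ]
    t <- tot$time_s
    f <- tot$fz
  }
  dt <- stats::median(diff(t))
  need <- max(1L, ceiling(debounce_s / dt))

  below <- f <= epsilon_n
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  events <- tibble::tibble(cycle = integer(), seat_off_s = numeric(),
                           reload_s = numeric())
  armed <- TRUE
  cyc <- 0L
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      if (armed && r$lengths[i] >= need) {
        j <- starts[i]
        cross <- if (j == 1) t[1] else {
          .sg_refine_crossing(t, f, j, epsilon_n)
        }
        cyc <- cyc + 1L
        events <- dplyr::bind_rows(events, tibble::tibble(
          cycle = cyc, seat_off_s = cross, reload_s = NA_real_))
        armed <- FALSE
      }
    } else {
      if (!armed && max(f[starts[i]:ends[i]]) > rearm_n) {
        k <- starts[i] - 1 + which(f[starts[i]:ends[i]] > rearm_n)[1]
        events$reload_s[nrow(events)] <- t[k]
        armed <- TRUE
      }
    }
  }
  abort_if(nrow(events) == 0,
           "no seat-off: rear-plate force never unloads below threshold",
           class = "standgaze_event_error")
  if (!is.null(expected) && nrow(events) < expected) {
    rlang::abort(sprintf(
      "expected %d seat-off events but found %d (at %s s)",
      expected, nrow(events),
      paste(sprintf("%.2f", events$seat_off_s), collapse = ", ")),
      class = "standgaze_event_error")
  }
  events
}

#' Detect maximum ankle dorsiflexion per rise
#'
#' Searches the (smoothed) dorsiflexion angle series within
#' `(seat_off_s, end_s]` of each cycle and returns the time of its maximum;
#' ties break to the earliest sample.
#'
#' @param angle tibble `time_s`, `angle_deg` from [ankle_angle()].
#' @param events seat-off event tibble from [detect_seat_off()]; its
#'   `reload_s` (or the end of the series) bounds the search.
#' @return tibble `cycle`, `t_max_dorsi_s`, `max_dorsi_deg`.
#' @export
detect_max_dorsiflexion <- function(angle, events) {
  t_end_all <- max(angle$time_s)
  purrr::map_dfr(seq_len(nrow(events)), function(k) {
    lo <- events$seat_off_s[k]
    hi <- if (is.na(events$reload_s[k])) t_end_all else events$reload_s[k]
    idx <- which(angle$time_s > lo & angle$time_s <= hi)
    abort_if(length(idx) == 0, "no samples after seat-off in this cycle",
             class = "standgaze_event_error")
    a <- angle$angle_deg[idx]
    i <- which.max(a)  # which.max returns the earliest maximum
    tibble::tibble(cycle = events$cycle[k],
                   t_max_dorsi_s = angle$time_s[idx][i],
                   max_dorsi_deg = a[i])
  })
}

# Sub-sample refinement of the downward threshold crossing between samples
# j-1 and j: local quadratic through the three samples ending at j (exact
# for linear ramps, second-order accurate on smooth decays); falls back to
# linear interpolation when no quadratic root lies in the bracket.
.sg_refine_crossing <- function(t, f, j, eps) {
  t0 <- t[j - 1]
  t1 <- t[j]
  linear <- t0 + (f[j - 1] - eps) / (f[j - 1] - f[j]) * (t1 - t0)
  if (j < 3) return(linear)
  ts <- t[(j - 2):j]
  fs <- f[(j - 2):j]
  # quadratic fit f(t) = c0 + c1 (t - t0) + c2 (t - t0)^2
  A <- cbind(1, ts - t0, (ts - t0)^2)
  cf <- tryCatch(solve(A, fs), error = function(e) NULL)
  if (is.null(cf)) return(linear)
  a <- cf[3]; b <- cf[2]; cc <- cf[1] - eps
  # near-collinear samples: the quadratic term is numerical noise
  if (abs(a) * (t1 - t0)^2 < 1e-9 * max(abs(b) * (t1 - t0), 1e-12)) {
    return(linear)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(linear)
  # numerically stable quadratic roots
  q <- -0.5 * (b + sign(b) * sqrt(disc))
  roots <- t0 + c(q / a, if (abs(q) > 0) cc / q else NA_real_)
  roots <- roots[is.finite(roots)]
  inside <- roots[roots >= t0 - 1e-12 & roots <= t1 + 1e-12]
  if (length(inside) == 0) return(linear)
  inside[1]
}

# Per-cycle analysis windows: each cycle spans from the midpoint of the
# preceding seated interval to the midpoint of the following one, so the
# lean, rise and sit of one cycle fall in exactly one window.
cycle_windows <- function(events, t_start, t_end) {
  n <- nrow(events)
  starts <- numeric(n)
  ends <- numeric(n)
  for (k in seq_len(n)) {
    starts[k] <- if (k == 1) t_start else {
      mean(c(events$reload_s[k - 1], events$seat_off_s[k]))
    }
    ends[k] <- if (k == n) t_end else {
      mean(c(events$reload_s[k], events$seat_off_s[k + 1]))
    }
  }
  tibble::tibble(cycle = events$cycle, start_s = starts, end_s = ends)
}
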