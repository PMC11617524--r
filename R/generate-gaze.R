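# Synthetic gaze streams: alternating fixation episodes (low-velocity point
# clusters inside an AOI band) and saccades (high-velocity jumps), scheduled
# so the realized per-AOI dwell fractions and fixation counts match the
# requested trial profile exactly on the sample grid.

#' Generate a synthetic gaze stream for one trial
#'
#' Builds a 50 Hz gaze stream over the support window in which, for each
#' AOI, `n_fix` fixation episodes are placed with total duration
#' `dwell_pct`% of the window. Episodes are positioned at a jittered point
#' inside the AOI band (evaluated at the episode midpoint, matching the
#' centroid-at-midpoint membership rule), separated by 2-sample saccades via
#' distant points; the remaining time is filled with off-AOI fixations in
#' the lower-shank strip that belongs to no AOI. Every episode is laid out
#' on the sample grid with a recoverable duration of at least 60 ms (the
#' I-VT floor), accounting for the arrival sample the filter discards.
#'
#' @param profile tibble `aoi`, `dwell_pct` (percent of window, sums to at
#'   most 100) and `n_fix` (requested fixation count, may be fractional --
#'   stochastically rounded).
#' @param layout AOI layout from [build_aoi_layout()].
#' @param window numeric `c(start_s, end_s)` of the support period.
#' @param rate sampling rate in Hz (default 50).
#' @param noise_sd within-fixation point jitter sd in metres.
#' @param seed optional integer seed.
#' @return tibble `time_ms`, `x`, `y`, `validity` with attribute `schedule`
#'   (the realized episode table).
#' @export
generate_gaze <- function(profile, layout, window, rate = 50,
                          noise_sd = 1e-3, seed = NULL) {
  abort_if(!all(c("aoi", "dwell_pct", "n_fix") %in% names(profile)),
           "profile needs columns aoi, dwell_pct, n_fix")
  abort_if(any(profile$dwell_pct < 0),
           "dwell fractions must be >= 0", class = "standgaze_validation_error")
  abort_if(sum(profile$dwell_pct) > 100 + 1e-9,
           "per-AOI dwell fractions sum to more than 100%",
           class = "standgaze_validation_error")
  abort_if(length(window) != 2 || diff(window) <= 0,
           "window must be c(start_s, end_s)",
           class = "standgaze_validation_error")

  dt <- 1 / rate
  W <- diff(window)
  N <- floor(W / dt) + 1
  # An episode of k samples is recovered by the I-VT filter without its
  # arrival sample (whose backward-difference velocity is saccadic), i.e.
  # with duration (k - 2) * dt; every episode therefore carries 2 extra
  # samples, and 5 samples give a recovered 60 ms, exactly the I-VT floor.
  min_ks <- 5

  with_sub_seed(seed %||% sub_seed(3, 17, 1), {
    episodes <- purrr::map_dfr(seq_len(nrow(profile)), function(i) {
      dwell <- profile$dwell_pct[i]
      if (dwell <= 0) return(NULL)
      T_i <- dwell / 100 * W
      nf <- profile$n_fix[i]
      k <- floor(nf) + stats::rbinom(1, 1, nf - floor(nf))
      k <- max(1L, as.integer(k))
      # keep every episode recoverable: at least (min_ks - 2) * dt long
      k <- max(1L, min(k, floor(T_i / ((min_ks - 2) * dt))))
      base <- (min_ks - 2) * dt
      excess <- pmax(stats::rgamma(k, shape = 1.5, rate = 1), 1e-6)
      spare <- max(T_i - k * base, 0)
      dur <- base + excess / sum(excess) * spare
      ks <- pmax(min_ks, round(dur / dt) + 2)
      # repair rounding drift so realized total dwell is exact in samples
      target <- round(T_i / dt) + 2L * k
      drift <- sum(ks) - target
      j <- 1
      while (drift != 0 && j <= 10 * k) {
        idx <- ((j - 1) %% k) + 1
        if (drift > 0 && ks[idx] > min_ks) {
          ks[idx] <- ks[idx] - 1; drift <- drift - 1
        } else if (drift < 0) {
          ks[idx] <- ks[idx] + 1; drift <- drift + 1
        }
        j <- j + 1
      }
      tibble::tibble(aoi = profile$aoi[i], ks = ks)
    })

    n_aoi_ep <- nrow(episodes)
    S_f <- if (n_aoi_ep) sum(episodes$ks) else 0L
    rem <- N - S_f - 2L * n_aoi_ep
    if (rem >= min_ks) {
      n_off <- max(1L, round(rem / 27))
      repeat {
        off_total <- N - S_f - 2L * (n_aoi_ep + n_off - 1L)
        if (off_total >= min_ks * n_off || n_off == 1L) break
        n_off <- n_off - 1L
      }
      if (off_total >= min_ks) {
        w <- stats::rgamma(n_off, 2, 1)
        ks_off <- pmax(min_ks, floor(off_total * w / sum(w)))
        # absorb the remainder into the first off episode
        ks_off[1] <- ks_off[1] + (off_total - sum(ks_off))
        if (ks_off[1] < min_ks) ks_off <- off_total  # fall back to one block
        episodes <- dplyr::bind_rows(
          episodes, tibble::tibble(aoi = "off", ks = ks_off))
      }
    }
    abort_if(nrow(episodes) == 0, "empty gaze schedule (window too short)")
    episodes <- episodes[sample.int(nrow(episodes)), ]

    # lay out samples: episode start indices, then vectorised placement
    n_ep <- nrow(episodes)
    ks_all <- episodes$ks
    start_idx <- 1L + c(0L, cumsum(ks_all[-n_ep] + 2L))
    total <- start_idx[n_ep] + ks_all[n_ep] - 1L
    tt <- window[1] + (seq_len(total) - 1) * dt
    mid_t <- tt[start_idx] + (ks_all - 1) / 2 * dt
    end_t <- tt[start_idx] + (ks_all - 1) * dt
    lab <- episodes$aoi
    # place each fixation inside the intersection of its band over the
    # episode's start, midpoint and end frames (the bands track the moving
    # body), with a safety margin so the centroid-at-midpoint rule can
    # never flip the label
    v0 <- numeric(n_ep)
    for (a in unique(lab)) {
      idx <- which(lab == a)
      # the label is decided by the centroid at the fixation midpoint, so
      # the point must sit inside the band around that time with a margin
      # covering the small midpoint shift the I-VT filter introduces
      iv_m <- .sg_band_interval(layout, mid_t[idx], a)
      iv_m1 <- .sg_band_interval(layout, mid_t[idx] - 0.03, a)
      iv_m2 <- .sg_band_interval(layout, mid_t[idx] + 0.03, a)
      glo <- pmax(iv_m$lo, iv_m1$lo, iv_m2$lo)
      ghi <- pmin(iv_m$hi, iv_m1$hi, iv_m2$hi)
      gmar <- pmax(0.005, pmin(0.15 * (ghi - glo), 0.03))
      glo2 <- glo + gmar
      ghi2 <- ghi - gmar
      # prefer staying inside the band over the whole episode (realistic
      # pursuit of the body part); otherwise the midpoint guard decides
      iv_s <- .sg_band_interval(layout, tt[start_idx[idx]], a)
      iv_e <- .sg_band_interval(layout, end_t[idx], a)
      lo <- pmax(glo2, iv_s$lo, iv_e$lo)
      hi <- pmin(ghi2, iv_s$hi, iv_e$hi)
      u <- stats::runif(length(idx))
      v0[idx] <- ifelse(hi > lo, lo + u * (hi - lo),
                        ifelse(ghi2 > glo2, glo2 + u * (ghi2 - glo2),
                               (glo + ghi) / 2))
    }
    u0 <- stats::runif(n_ep, -0.05, 0.05)

    y <- numeric(total)
    x <- numeric(total)
    in_ep <- logical(total)
    for (e in seq_len(n_ep)) {
      idx <- start_idx[e]:(start_idx[e] + ks_all[e] - 1L)
      in_ep[idx] <- TRUE
      y[idx] <- v0[e]
      x[idx] <- u0[e]
    }
    n_fixsamp <- sum(in_ep)
    y[in_ep] <- y[in_ep] + stats::rnorm(n_fixsamp, 0, noise_sd)
    x[in_ep] <- x[in_ep] + stats::rnorm(n_fixsamp, 0, noise_sd)
    # saccade samples: far positions, kept >= 0.15 m away from both the
    # previous and following fixation points
    sac <- which(!in_ep)
    if (length(sac) > 0) {
      prev_ep <- findInterval(sac, start_idx)          # episode before
      next_v <- v0[pmin(prev_ep + 1L, n_ep)]
      prev_v <- v0[pmax(prev_ep, 1L)]
      vs <- stats::runif(length(sac), -0.4, 2.2)
      bad <- abs(vs - prev_v) < 0.15 | abs(vs - next_v) < 0.15
      tries <- 0
      while (any(bad) && tries < 25) {
        vs[bad] <- stats::runif(sum(bad), -0.4, 2.2)
        bad <- abs(vs - prev_v) < 0.15 | abs(vs - next_v) < 0.15
        tries <- tries + 1
      }
      # consecutive saccade pairs must also be far apart
      pair2 <- sac[c(FALSE, diff(sac) == 1L)]
      close_pair <- abs(vs[match(pair2, sac)] - vs[match(pair2 - 1L, sac)]) < 0.15
      vs[match(pair2, sac)][close_pair] <-
        vs[match(pair2, sac)][close_pair] + 0.4
      y[sac] <- vs
      x[sac] <- stats::runif(length(sac), -0.2, 0.2)
    }
    out <- tibble::tibble(time_ms = round(tt * 1000, 3), x = x, y = y,
                          validity = 1L)
    attr(out, "rate") <- rate
    attr(out, "schedule") <- tibble::tibble(
      aoi = lab, start_ms = tt[start_idx] * 1000,
      duration_ms = (ks_all - 1) * dt * 1000, v = v0)
    out
  })
}
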