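# Shared fixtures, all generated in code.

# A short single-cycle script for fast unit tests.
quick_script <- function(peak = 35, vel = 0.45, bos = -0.03, cycles = 1,
                         ...) {
  motion_script(peak_flexion_deg = peak, com_velocity_ms = vel,
                com_bos_m = bos, cycles = cycles,
                lead_s = 0.5, seated_s = 0.4, lean_s = 0.8, hold_s = 0.3,
                rise_s = 0.8, stand_s = 0.4, sit_s = 0.9, tail_s = 0.5,
                dorsi_peak_after_s = 0.35, grf_decay_s = 0.3, ...)
}

# A full synthetic trial built around a script.
quick_trial <- function(script = quick_script(), mass = 60,
                        marker_noise = 0, grf_noise = 0, seed = 1) {
  markers <- generate_motion(script, default_skeleton(mass),
                             noise_sd = marker_noise, seed = seed)
  grf <- generate_grf(script, mass, noise_sd = grf_noise, seed = seed + 1)
  structure(list(
    markers = markers, grf = grf, gaze = NULL,
    meta = list(rear_plates = c(5L, 6L), release_s = script$release_s,
                script = list(cycles = script$cycles,
                              peak_flexion_deg = script$peak_flexion_deg,
                              com_velocity_ms = script$com_velocity_ms,
                              com_bos_m = script$com_bos_m))),
    class = "sg_trial")
}

# One standing frame of the default skeleton as a marker tibble.
static_frame <- function(theta = 0, phi = 4, beta = 6, dy = 0) {
  M <- standgaze:::fk_markers(theta, phi, beta, dy, default_skeleton())
  out <- tibble::as_tibble(as.data.frame(M))
  tibble::add_column(out, frame = 1L, time_s = 0, .before = 1)
}

# A static marker "trajectory" (constant pose) over n frames at 100 Hz.
static_markers <- function(n = 50, theta = 0) {
  M <- standgaze:::fk_markers(rep(theta, n), rep(4, n), rep(6, n),
                              rep(0, n), default_skeleton())
  out <- tibble::as_tibble(as.data.frame(M))
  out <- tibble::add_column(out, frame = seq_len(n),
                            time_s = (seq_len(n) - 1) / 100, .before = 1)
  attr(out, "rate") <- 100
  out
}

# Apply a rigid rotation about the lab z-axis plus translation to every
# marker of a frame/trajectory.
rigid_transform <- function(markers, deg_z = 0, shift = c(0, 0, 0)) {
  R <- rotation_z(deg_z)
  out <- markers
  nms <- unique(sub("_(x|y|z)$", "",
                    grep("_(x|y|z)$", names(markers), value = TRUE)))
  for (m in nms) {
    p <- rbind(markers[[paste0(m, "_x")]], markers[[paste0(m, "_y")]],
               markers[[paste0(m, "_z")]])
    q <- R %*% p + shift
    out[[paste0(m, "_x")]] <- q[1, ]
    out[[paste0(m, "_y")]] <- q[2, ]
    out[[paste0(m, "_z")]] <- q[3, ]
  }
  out
}

# Brute-force I-VT classification: explicit per-sample loop.
ivt_oracle <- function(gaze, thr = 30, min_dur = 60, dist = 1) {
  n <- nrow(gaze)
  lab <- logical(n)
  for (j in seq_len(n)) {
    if (j == 1) next
    dt <- (gaze$time_ms[j] - gaze$time_ms[j - 1]) / 1000
    d <- sqrt((gaze$x[j] - gaze$x[j - 1])^2 + (gaze$y[j] - gaze$y[j - 1])^2)
    v <- atan2(d, dist) * 180 / pi / dt
    lab[j] <- v <= thr
  }
  if (n >= 2) lab[1] <- lab[2]
  fixes <- list()
  j <- 1
  while (j <= n) {
    if (!lab[j]) { j <- j + 1; next }
    k <- j
    while (k < n && lab[k + 1]) k <- k + 1
    dur <- gaze$time_ms[k] - gaze$time_ms[j]
    if (dur >= min_dur) {
      fixes[[length(fixes) + 1]] <- data.frame(
        start_ms = gaze$time_ms[j], duration_ms = dur,
        x = mean(gaze$x[j:k]), y = mean(gaze$y[j:k]))
    }
    j <- k + 1
  }
  if (length(fixes) == 0) {
    return(data.frame(start_ms = numeric(), duration_ms = numeric(),
                      x = numeric(), y = numeric()))
  }
  do.call(rbind, fixes)
}

# Random piecewise-constant gaze stream with occasional jumps.
random_gaze_stream <- function(n = 60, rate = 50) {
  t <- (seq_len(n) - 1) * 1000 / rate
  y <- numeric(n)
  x <- numeric(n)
  pos <- stats::runif(2, -0.5, 0.5)
  for (j in seq_len(n)) {
    if (stats::runif(1) < 0.15) pos <- stats::runif(2, -0.5, 0.5)
    x[j] <- pos[1] + stats::rnorm(1, 0, 2e-3)
    y[j] <- pos[2] + stats::rnorm(1, 0, 2e-3)
  }
  tibble::tibble(time_ms = t, x = x, y = y, validity = 1L)
}
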