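# Synthetic marker-trajectory generation: a planar (sagittal) articulated
# chain driven by minimum-jerk joint-angle profiles, calibrated per trial so
# that the pipeline-recoverable indices equal their scripted values.

# Fixed posture constants of the motion model (degrees).
.sg_pose <- list(
  phi_rise_max = 26, # scripted dorsiflexion peak during the rise
  phi_stand = 4,
  phi_sit_bump = 20,
  beta_seated = 78,  # thigh-from-vertical while seated
  beta_stand = 6,    # thigh-from-vertical when standing
  sit_flexion_frac = 0.9, # sit-down lean relative to the stand-up peak
  pelvis_gain = 0.35,     # pelvic tilt as a fraction of trunk flexion
  theta_stand_frac = 0.2  # residual trunk tilt at full stand
)

# Marker local-offset definitions. `frame` is the segment the offset is
# expressed in: trunk/pelvis rotate about the lab x-axis, "leg" markers are
# derived from joint centres, "foot" markers are ground-fixed.
.sg_marker_defs <- function(sk) {
  tl <- sk$trunk_len
  hw <- sk$shoulder_halfwidth
  ft <- sk$foot
  list(
    # trunk-frame offsets (origin mid-hip), symmetric so that the
    # reconstructed trunk axis is the local z-axis exactly
    CLAV = list(frame = "trunk", off = c(0, 0.06, 0.96 * tl)),
    T2   = list(frame = "trunk", off = c(0, -0.06, 0.96 * tl)),
    STRN = list(frame = "trunk", off = c(0, 0.07, 0.62 * tl)),
    T7   = list(frame = "trunk", off = c(0, -0.07, 0.62 * tl)),
    LSHO = list(frame = "trunk", off = c(-hw, 0, tl)),
    RSHO = list(frame = "trunk", off = c(hw, 0, tl)),
    LFHD = list(frame = "trunk", off = c(-0.08, 0.11, tl + sk$head_off + 0.04)),
    RFHD = list(frame = "trunk", off = c(0.08, 0.11, tl + sk$head_off + 0.04)),
    LBHD = list(frame = "trunk", off = c(-0.08, -0.07, tl + sk$head_off + 0.04)),
    RBHD = list(frame = "trunk", off = c(0.08, -0.07, tl + sk$head_off + 0.04)),
    LELB = list(frame = "trunk", off = c(-hw - 0.02, 0.05, tl - 0.28)),
    RELB = list(frame = "trunk", off = c(hw + 0.02, 0.05, tl - 0.28)),
    LWRI = list(frame = "trunk", off = c(-hw - 0.03, 0.09, tl - 0.53)),
    RWRI = list(frame = "trunk", off = c(hw + 0.03, 0.09, tl - 0.53)),
    # pelvis-frame offsets (origin mid-hip, rotates with pelvic tilt)
    LASI = list(frame = "pelvis", off = c(-0.12, 0.09, 0.05)),
    RASI = list(frame = "pelvis", off = c(0.12, 0.09, 0.05)),
    LPSI = list(frame = "pelvis", off = c(-0.05, -0.10, 0.06)),
    RPSI = list(frame = "pelvis", off = c(0.05, -0.10, 0.06)),
    SJ1  = list(frame = "pelvis", off = c(0, -0.15, 0.10)),
    SJ2  = list(frame = "pelvis", off = c(-0.05, -0.17, 0.03)),
    SJ3  = list(frame = "pelvis", off = c(0.05, -0.17, 0.03)),
    # leg markers from joint centres
    LHIP = list(frame = "leg", joint = "hip", x = -0.11),
    RHIP = list(frame = "leg", joint = "hip", x = 0.11),
    LTHI = list(frame = "leg", joint = "midthigh", x = -0.13),
    RTHI = list(frame = "leg", joint = "midthigh", x = 0.13),
    LKNE = list(frame = "leg", joint = "knee", x = -0.16),
    RKNE = list(frame = "leg", joint = "knee", x = 0.16),
    LTIB = list(frame = "leg", joint = "midshank", x = -0.18),
    RTIB = list(frame = "leg", joint = "midshank", x = 0.18),
    LANK = list(frame = "leg", joint = "ankle", x = -0.13),
    RANK = list(frame = "leg", joint = "ankle", x = 0.13),
    # ground-fixed foot markers
    LHEE = list(frame = "foot", off = c(-0.10, ft$heel_y, ft$heel_z)),
    RHEE = list(frame = "foot", off = c(0.10, ft$heel_y, ft$heel_z)),
    LTOE = list(frame = "foot", off = c(-0.08, ft$toe_y, ft$toe_z)),
    RTOE = list(frame = "foot", off = c(0.08, ft$toe_y, ft$toe_z)),
    LMT5 = list(frame = "foot", off = c(-0.15, ft$mt5_y, 0.02)),
    RMT5 = list(frame = "foot", off = c(0.15, ft$mt5_y, 0.02))
  )
}

# Vectorised forward kinematics: angle vectors (degrees) and a whole-body
# forward offset dy (m) -> n x (37*3) matrix of marker positions, columns
# <MKR>_x/_y/_z in marker_set() order.
fk_markers <- function(theta_deg, phi_deg, beta_deg, dy, skeleton) {
  n <- length(theta_deg)
  d2r <- pi / 180
  th <- theta_deg * d2r
  ph <- phi_deg * d2r
  be <- beta_deg * d2r
  rho <- (.sg_pose$pelvis_gain * theta_deg + 5) * d2r

  sk <- skeleton
  knee_y <- sk$shank_len * sin(ph)
  knee_z <- sk$ankle_h + sk$shank_len * cos(ph)
  hip_y <- knee_y - sk$thigh_len * sin(be)
  hip_z <- knee_z + sk$thigh_len * cos(be)

  ct <- cos(th); st <- sin(th)
  cr <- cos(rho); sr <- sin(rho)

  defs <- .sg_marker_defs(sk)
  nm <- marker_set()
  out <- matrix(NA_real_, n, 3 * length(nm))
  colnames(out) <- paste0(rep(nm, each = 3), "_", c("x", "y", "z"))

  for (m in nm) {
    d <- defs[[m]]
    if (d$frame == "trunk") {
      o <- d$off
      x <- rep(o[1], n)
      y <- hip_y + o[2] * ct + o[3] * st + dy
      z <- hip_z - o[2] * st + o[3] * ct
    } else if (d$frame == "pelvis") {
      o <- d$off
      x <- rep(o[1], n)
      y <- hip_y + o[2] * cr + o[3] * sr + dy
      z <- hip_z - o[2] * sr + o[3] * cr
    } else if (d$frame == "foot") {
      o <- d$off
      x <- rep(o[1], n)
      y <- rep(o[2], n) + dy
      z <- rep(o[3], n)
    } else {
      x <- rep(d$x, n)
      jy <- switch(d$joint,
        ankle = rep(0, n), knee = knee_y, hip = hip_y,
        midshank = knee_y / 2, midthigh = (knee_y + hip_y) / 2)
      jz <- switch(d$joint,
        ankle = rep(sk$ankle_h, n), knee = knee_z, hip = hip_z,
        midshank = (sk$ankle_h + knee_z) / 2, midthigh = (knee_z + hip_z) / 2)
      y <- jy + dy
      z <- jz
    }
    out[, paste0(m, "_x")] <- x
    out[, paste0(m, "_y")] <- y
    out[, paste0(m, "_z")] <- z
  }
  out
}

# COM of an fk matrix (or any wide marker matrix) via the segment table.
com_from_matrix <- function(M, segments = de_leva_segments()) {
  centroid <- function(markers, axis) {
    cols <- paste0(markers, "_", axis)
    if (length(cols) == 1L) M[, cols] else rowMeans(M[, cols, drop = FALSE])
  }
  acc <- matrix(0, nrow(M), 3)
  for (i in seq_len(nrow(segments))) {
    f <- segments$com_frac[i]
    w <- segments$mass_frac[i]
    for (j in 1:3) {
      ax <- c("x", "y", "z")[j]
      p <- centroid(segments$proximal[[i]], ax)
      d <- centroid(segments$distal[[i]], ax)
      acc[, j] <- acc[, j] + w * (p + f * (d - p))
    }
  }
  colnames(acc) <- c("x", "y", "z")
  acc
}

# Scripted joint-angle profiles over an absolute time grid. The seated
# shank angle (foot placement relative to the body) is the calibrated
# degree of freedom that sets the COM-BOS distance at seat-off.
.sg_angle_profiles <- function(t, script, phi_seated) {
  s <- script
  p <- .sg_pose
  P <- s$peak_flexion_deg
  rel_lean <- s$seated_s
  rel_lean_end <- s$seated_s + s$lean_s
  rel_hold_end <- rel_lean_end + s$hold_s
  rel_so <- rel_lean_end + s$hold_s / 2
  rel_rise_end <- rel_hold_end + s$rise_s
  rel_sit_start <- rel_rise_end + s$stand_s
  rel_sit_end <- rel_sit_start + s$sit_s

  # the deepest flexion is reached at the end of the lean and relaxes
  # slightly through the hold, so the per-cycle maximum is unique and
  # always precedes seat-off even under measurement noise
  theta_k <- list(
    t = c(0, rel_lean, rel_lean_end, rel_hold_end,
          rel_rise_end, rel_sit_start, rel_sit_start + 0.55 * s$sit_s,
          rel_sit_end),
    v = c(0, 0, P, 0.97 * P, p$theta_stand_frac * P,
          p$theta_stand_frac * P, p$sit_flexion_frac * P, 0))
  phi_k <- list(
    t = c(0, rel_so, rel_so + s$dorsi_peak_after_s, rel_rise_end,
          rel_sit_start, rel_sit_start + 0.6 * s$sit_s, rel_sit_end),
    v = c(phi_seated, phi_seated, p$phi_rise_max, p$phi_stand,
          p$phi_stand, p$phi_sit_bump, phi_seated))
  beta_k <- list(
    t = c(0, rel_so, rel_rise_end, rel_sit_start, rel_sit_end),
    v = c(p$beta_seated, p$beta_seated, p$beta_stand, p$beta_stand,
          p$beta_seated))

  eval_profile <- function(k, base) {
    v <- rep(base, length(t))
    for (cs in s$cycle_start_s) {
      idx <- t >= cs & t <= cs + s$cycle_len_s + 1e-12
      v[idx] <- mjerk_profile(t[idx] - cs, k$t, k$v)
    }
    v
  }
  list(theta = eval_profile(theta_k, 0),
       phi = eval_profile(phi_k, phi_seated),
       beta = eval_profile(beta_k, p$beta_seated))
}

# Seated-pose COM-BOS distance as a function of the seated shank angle,
# evaluated at the trunk angle actually held at the seat-off reference.
.sg_combos_at_seatoff <- function(phi_seated, theta_so, skeleton, segments) {
  M <- fk_markers(theta_so, phi_seated, .sg_pose$beta_seated,
                  0, skeleton)
  com <- com_from_matrix(M, segments)
  heel <- min(M[, "LHEE_y"], M[, "RHEE_y"])
  com[1, "y"] - heel
}

#' Generate synthetic marker trajectories for one trial
#'
#' Realises a [motion_script()] as 37 marker trajectories of a planar
#' articulated body performing repeated assisted stand/sit cycles. Joint
#' angles follow minimum-jerk profiles. Two per-trial calibrations make the
#' scripted indices exact at zero noise: the seated thigh angle is solved so
#' that the COM-to-heel distance at seat-off equals `script$com_bos_m`, and a
#' smooth whole-body forward translation inside each rise makes the COM
#' forward travel between seat-off and maximum dorsiflexion equal
#' `script$com_velocity_ms` times the window length (a rigid translation, so
#' no joint or trunk angle is disturbed).
#'
#' ASIS markers are blanked (missing, not zero) whenever trunk flexion
#' exceeds `occlusion_threshold_deg`, emulating occlusion of the pelvis by
#' the forward-bent torso.
#'
#' @param script a [motion_script()].
#' @param skeleton a [default_skeleton()].
#' @param rate marker sampling rate in Hz (default 100).
#' @param segments body segment parameter table, see [de_leva_segments()].
#' @param noise_sd additive white marker noise sd in metres (0 = noiseless).
#' @param occlusion_threshold_deg trunk flexion above which the ASIS markers
#'   are occluded.
#' @param seed optional integer seed for the noise stream.
#' @return tibble with columns `frame`, `time_s` and `<MARKER>_<x|y|z>` for
#'   the 37 markers, with attributes `rate`, `events` (per-cycle seat-off /
#'   max-dorsiflexion times) and `script`.
#' @export
#' @examples
#' m <- generate_motion(motion_script(cycles = 1), default_skeleton(),
#'                      noise_sd = 0)
#' range(m$time_s)
generate_motion <- function(script, skeleton = default_skeleton(), rate = 100,
                            segments = de_leva_segments(),
                            noise_sd = 5e-4, occlusion_threshold_deg = 25,
                            seed = NULL) {
  validate_script(script)
  validate_segments(segments)
  abort_if(!is.numeric(rate) || rate <= 0, "rate must be > 0 Hz")

  t <- seq(0, script$duration_s, by = 1 / rate)

  # seat-off reference: where the rear-plate load crosses the detector's
  # threshold. With the minimum-jerk unloading F = F0 (1 - s(tau)) the
  # threshold eps sits u* decay-lengths before the scripted zero, where u*
  # solves 10u^3 - 15u^4 + 6u^5 = eps / F0.
  fw0 <- script$grf_seated_frac * skeleton$mass_kg * 9.80665
  u_star <- stats::uniroot(
    function(u) 10 * u^3 - 15 * u^4 + 6 * u^5 - script$seatoff_ref_n / fw0,
    c(0, 1), tol = 1e-12)$root
  t_so_eff <- script$seat_off_s - script$grf_decay_s * u_star

  # trunk angle held at the seat-off reference (slight relaxation from the
  # lean peak through the hold phase)
  P <- script$peak_flexion_deg
  tau_hold <- (t_so_eff[1] - (script$cycle_start_s[1] + script$seated_s +
                                script$lean_s)) / script$hold_s
  theta_so <- P + (0.97 * P - P) * mjerk(tau_hold)

  # --- calibration 1: seated shank angle -> COM-BOS at seat-off ---
  target <- script$com_bos_m
  dev_at <- function(phi) {
    .sg_combos_at_seatoff(phi, theta_so, skeleton, segments) - target
  }
  lo <- -10; hi <- 23
  f_lo <- dev_at(lo); f_hi <- dev_at(hi)
  if (f_lo * f_hi > 0) {
    # target outside the reachable seated range: take the closest posture
    phi_seated <- if (abs(f_lo) < abs(f_hi)) lo else hi
    rlang::warn(sprintf(
      "COM-BOS target %+.3f m outside the reachable seated range (residual %+.4f m)",
      target, min(abs(f_lo), abs(f_hi)) * sign(if (abs(f_lo) < abs(f_hi)) f_lo else f_hi)))
  } else {
    phi_seated <- stats::uniroot(dev_at, c(lo, hi), tol = 1e-8)$root
  }

  ang <- .sg_angle_profiles(t, script, phi_seated)

  # --- calibration 2: whole-body forward ramp -> COM velocity ---
  t_md <- script$dorsi_peak_s
  com_y_at <- function(tt) {
    a <- .sg_angle_profiles(tt, script, phi_seated)
    M <- fk_markers(a$theta, a$phi, a$beta, 0, skeleton)
    com_from_matrix(M, segments)[, "y"]
  }
  y_ends <- com_y_at(c(t_so_eff[1], t_md[1]))
  amp <- script$com_velocity_ms * (t_md[1] - t_so_eff[1]) -
    (y_ends[2] - y_ends[1])

  dy <- numeric(length(t))
  rel_sit_start <- script$sit_start_s - script$cycle_start_s
  rel_sit_end <- script$sit_end_s - script$cycle_start_s
  for (k in seq_len(script$cycles)) {
    cs <- script$cycle_start_s[k]
    idx <- t >= cs & t <= cs + script$cycle_len_s + 1e-12
    dy[idx] <- mjerk_profile(
      t[idx] - cs,
      c(0, t_so_eff[k] - cs, t_md[k] - cs,
        rel_sit_start[k] + 0.1, rel_sit_end[k] - 0.05),
      c(0, 0, amp, amp, 0))
  }

  M <- fk_markers(ang$theta, ang$phi, ang$beta, dy, skeleton)

  if (noise_sd > 0) {
    noise <- with_sub_seed(seed %||% sub_seed(1, 7, 1), {
      matrix(stats::rnorm(length(M), 0, noise_sd), nrow(M))
    })
    M <- M + noise
  }
  occluded <- ang$theta > occlusion_threshold_deg
  if (any(occluded)) {
    M[occluded, c("LASI_x", "LASI_y", "LASI_z",
                  "RASI_x", "RASI_y", "RASI_z")] <- NA_real_
  }

  out <- tibble::as_tibble(as.data.frame(M))
  out <- tibble::add_column(out, frame = seq_along(t), time_s = t,
                            .before = 1)
  attr(out, "rate") <- rate
  attr(out, "events") <- tibble::tibble(
    cycle = seq_len(script$cycles),
    lean_onset_s = script$lean_onset_s,
    seat_off_s = script$seat_off_s,
    seat_off_eff_s = t_so_eff,
    dorsi_peak_s = t_md,
    sit_end_s = script$sit_end_s)
  attr(out, "script") <- script
  out
}
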