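# Rigid-body stage: COM, angles, virtual ASIS, events.

test_that("segment table conserves mass and rejects invalid fractions", {
  seg <- de_leva_segments()
  expect_equal(sum(seg$mass_frac), 1, tolerance = 1e-9)
  bad <- seg
  bad$mass_frac[1] <- bad$mass_frac[1] + 0.1
  expect_error(whole_body_com(static_markers(2), bad), "sum to 1")
  bad2 <- seg
  bad2$com_frac[1] <- 1.4
  expect_error(whole_body_com(static_markers(2), bad2), "\\[0, 1\\]")
})

test_that("whole-body COM equals a direct weighted sum on random poses", {
  set.seed(42)
  for (r in 1:20) {
    mk <- static_frame(theta = stats::runif(1, 0, 45),
                       phi = stats::runif(1, 0, 25),
                       beta = stats::runif(1, 5, 85),
                       dy = stats::runif(1, -0.2, 0.2))
    mk[grep("_(x|y|z)$", names(mk))] <-
      mk[grep("_(x|y|z)$", names(mk))] +
      stats::rnorm(3 * 37, 0, 0.01)  # jitter off the scripted pose
    com <- whole_body_com(mk)
    # oracle: independent summation loop over the segment table
    seg <- de_leva_segments()
    truth <- c(0, 0, 0)
    for (i in seq_len(nrow(seg))) {
      pt <- function(markers, ax) {
        mean(vapply(markers, function(m) mk[[paste0(m, "_", ax)]],
                    numeric(1)))
      }
      for (j in 1:3) {
        ax <- c("x", "y", "z")[j]
        p <- pt(seg$proximal[[i]], ax)
        d <- pt(seg$distal[[i]], ax)
        truth[j] <- truth[j] +
          seg$mass_frac[i] * (p + seg$com_frac[i] * (d - p))
      }
    }
    expect_equal(c(com$com_x, com$com_y, com$com_z), truth,
                 tolerance = 1e-12)
  }
})

test_that("degenerate segment layouts give the obvious COM", {
  # two equal-mass segments at distinct points, everything else ignored
  seg <- tibble::tibble(
    segment = c("a", "b"),
    proximal = list("P1", "P2"), distal = list("P1", "P2"),
    mass_frac = c(0.5, 0.5), com_frac = c(0.5, 0.5))
  mk <- tibble::tibble(time_s = 0,
                       P1_x = 0, P1_y = 0, P1_z = 0,
                       P2_x = 1, P2_y = 0, P2_z = 0)
  com <- whole_body_com(mk, seg)
  expect_equal(c(com$com_x, com$com_y, com$com_z), c(0.5, 0, 0))
})

test_that("COM transforms rigidly with the whole pose", {
  mk <- static_frame(theta = 25, phi = 15, beta = 60)
  com0 <- whole_body_com(mk)
  mk2 <- rigid_transform(mk, deg_z = 40, shift = c(0.3, -0.2, 0.1))
  com1 <- whole_body_com(mk2)
  p <- rotation_z(40) %*% c(com0$com_x, com0$com_y, com0$com_z) +
    c(0.3, -0.2, 0.1)
  expect_equal(c(com1$com_x, com1$com_y, com1$com_z), as.numeric(p),
               tolerance = 1e-12)
})

test_that("missing landmarks are reported by segment name", {
  mk <- static_markers(3)
  mk$LKNE_x[2] <- NA
  expect_error(whole_body_com(mk), "thigh_l",
               class = "standgaze_landmark_error")
})

test_that("Cardan decomposition recovers composed rotations", {
  R <- rotation_x(10) %*% rotation_y(5) %*% rotation_z(5)
  expect_equal(unname(cardan_xyz(R)), c(10, 5, 5), tolerance = 1e-6)
  set.seed(3)
  for (r in 1:20) {
    a <- stats::runif(3, -40, 40)
    R <- rotation_x(a[1]) %*% rotation_y(a[2]) %*% rotation_z(a[3])
    expect_equal(unname(cardan_xyz(R)), a, tolerance = 1e-9)
  }
})

test_that("trunk angle reads 0 upright and the constructed tilt otherwise", {
  up <- trunk_angle(static_markers(2, theta = 0))
  expect_equal(up$angle_deg, c(0, 0), tolerance = 1e-9)

  tilted <- trunk_angle(static_markers(2, theta = 30))
  expect_equal(tilted$angle_deg, c(30, 30), tolerance = 1e-9)

  # explicit forward rotation of upright trunk markers about the x-axis
  mk <- static_frame(theta = 0)
  fwd <- function(deg) {
    out <- mk
    for (m in c("CLAV", "STRN", "T2", "T7")) {
      p <- c(mk[[paste0(m, "_x")]], mk[[paste0(m, "_y")]],
             mk[[paste0(m, "_z")]])
      # tip the top toward +y (forward lean) by deg
      q <- rotation_x(-deg) %*% p
      out[[paste0(m, "_x")]] <- q[1]
      out[[paste0(m, "_y")]] <- q[2]
      out[[paste0(m, "_z")]] <- q[3]
    }
    out
  }
  expect_equal(trunk_angle(fwd(30))$angle_deg, 30, tolerance = 1e-6)
})

test_that("virtual ASIS calibration is frame invariant and exact", {
  frame <- static_frame(theta = 5, phi = 10, beta = 75)
  pose <- calibrate_virtual_asis(frame)

  moved <- rigid_transform(frame, deg_z = 33, shift = c(0.5, 1.2, -0.1))
  pose2 <- calibrate_virtual_asis(moved)
  expect_equal(pose$LASI, pose2$LASI, tolerance = 1e-9)
  expect_equal(pose$RASI, pose2$RASI, tolerance = 1e-9)

  # reconstruction after a random rigid motion matches the true transform
  set.seed(11)
  for (r in 1:10) {
    deg <- stats::runif(1, -60, 60)
    sh <- stats::rnorm(3, 0, 0.5)
    moved <- rigid_transform(frame, deg_z = deg, shift = sh)
    truthL <- c(moved$LASI_x, moved$LASI_y, moved$LASI_z)
    moved$LASI_x <- NA; moved$LASI_y <- NA; moved$LASI_z <- NA
    rec <- reconstruct_asis(moved, pose)
    expect_equal(c(rec$LASI_x, rec$LASI_y, rec$LASI_z), truthL,
                 tolerance = 1e-9)
  }
})

test_that("collinear jig markers are rejected", {
  frame <- static_frame()
  # move SJ3 onto the SJ1-SJ2 line
  frame$SJ3_x <- 2 * frame$SJ2_x - frame$SJ1_x
  frame$SJ3_y <- 2 * frame$SJ2_y - frame$SJ1_y
  frame$SJ3_z <- 2 * frame$SJ2_z - frame$SJ1_z
  expect_error(calibrate_virtual_asis(frame), "collinear",
               class = "standgaze_validation_error")
})

test_that("visible ASIS is kept and its discrepancy reported", {
  n <- 20
  mk <- static_markers(n, theta = 10)
  pose <- calibrate_virtual_asis(mk[1, ])
  mk$LASI_x[5:10] <- NA; mk$LASI_y[5:10] <- NA; mk$LASI_z[5:10] <- NA
  rec <- reconstruct_asis(mk, pose)
  expect_false(anyNA(rec$LASI_x))
  expect_lt(attr(rec, "asis_quality"), 1e-9)
  expect_equal(attr(rec, "asis_unrecoverable"), 0L)
})

test_that("seat-off interpolates the threshold crossing on a linear ramp", {
  # 200 N -> 0 over [1 s, 2 s] at 100 Hz, epsilon = 5 N: crossing at 1.975 s
  t <- seq(0, 3, by = 0.01)
  fz <- ifelse(t < 1, 200, ifelse(t < 2, 200 * (2 - t), 0))
  grf <- tibble::tibble(time_s = rep(t, 2), plate = rep(5:6, each = length(t)),
                        fz = rep(fz / 2, 2))
  ev <- detect_seat_off(grf, rear_plates = 5:6, epsilon_n = 5)
  expect_equal(ev$seat_off_s, 1.975, tolerance = 1e-9)

  # random ramps vs the brute-force linear-interpolation oracle
  set.seed(21)
  for (r in 1:15) {
    f0 <- stats::runif(1, 100, 600)
    t1 <- stats::runif(1, 0.5, 1.5)
    dur <- stats::runif(1, 0.3, 1.5)
    # keep the crossing more than one sample above the ramp-end corner
    eps <- stats::runif(1, 0.05, 0.15) * f0
    fz <- ifelse(t < t1, f0, pmax(0, f0 * (1 - (t - t1) / dur)))
    grf <- tibble::tibble(time_s = t, plate = 5L, fz = fz)
    ev <- detect_seat_off(grf, rear_plates = 5L, epsilon_n = eps)
    truth <- t1 + dur * (1 - eps / f0)
    expect_equal(ev$seat_off_s, truth, tolerance = 1e-6)
  }
})

test_that("seat-off errors when the force never unloads", {
  t <- seq(0, 2, by = 0.01)
  grf <- tibble::tibble(time_s = t, plate = 5L, fz = 300 + 5 * sin(t))
  expect_error(detect_seat_off(grf, rear_plates = 5L),
               "no seat-off", class = "standgaze_event_error")
})

test_that("fewer events than expected lists the cycles found", {
  t <- seq(0, 3, by = 0.01)
  fz <- ifelse(t < 1, 200, ifelse(t < 2, 200 * (2 - t), 0))
  grf <- tibble::tibble(time_s = t, plate = 5L, fz = fz)
  expect_error(detect_seat_off(grf, rear_plates = 5L, expected = 5),
               "expected 5 .* found 1", class = "standgaze_event_error")
})

test_that("max dorsiflexion takes the earliest maximum in the window", {
  t <- seq(0, 3, by = 0.01)
  # monotone rise to a plateau: first plateau sample wins
  a <- pmin(20, 10 * t)
  ang <- tibble::tibble(time_s = t, angle_deg = a)
  ev <- tibble::tibble(cycle = 1L, seat_off_s = 0.5, reload_s = NA_real_)
  md <- detect_max_dorsiflexion(ang, ev)
  expect_equal(md$t_max_dorsi_s, 2.00, tolerance = 1e-9)

  # unimodal peak at a scripted time
  a2 <- 15 - (t - 2.4)^2 * 10
  md2 <- detect_max_dorsiflexion(tibble::tibble(time_s = t, angle_deg = a2),
                                 ev)
  expect_equal(md2$t_max_dorsi_s, 2.4, tolerance = 1e-9)

  # noisy series equals the brute-force argmax of the same series
  set.seed(5)
  a3 <- a2 + stats::rnorm(length(t), 0, 0.5)
  md3 <- detect_max_dorsiflexion(tibble::tibble(time_s = t, angle_deg = a3),
                                 ev)
  idx <- which(t > 0.5)
  expect_equal(md3$t_max_dorsi_s, t[idx][which.max(a3[idx])])
})

test_that("com_velocity is plain displacement over time and validates windows", {
  com <- tibble::tibble(time_s = seq(0, 1, by = 0.01),
                        com_y = seq(0, 1, by = 0.01) * 0.4)
  expect_equal(com_velocity(com, 0.2, 0.7), 0.4, tolerance = 1e-9)

  still <- tibble::tibble(time_s = seq(0, 1, by = 0.01), com_y = 0.3)
  expect_equal(com_velocity(still, 0.1, 0.9), 0)

  # 0.10 m in 0.25 s -> 0.40 m/s
  com2 <- tibble::tibble(time_s = c(0, 0.25), com_y = c(0, 0.10))
  expect_equal(com_velocity(com2, 0, 0.25), 0.4)
  expect_error(com_velocity(com, 0.5, 0.5), "zero-length",
               class = "standgaze_validation_error")
})

test_that("com_bos_distance is the signed forward heel-to-COM gap", {
  mk <- static_markers(5)
  com <- whole_body_com(mk)
  heel <- min(mk$LHEE_y, mk$RHEE_y)
  d <- com_bos_distance(mk, 0.02, com = com)
  expect_equal(d, com$com_y[1] - heel, tolerance = 1e-9)

  # constructed cases with a segment table that does not involve the heel,
  # so moving the heel line moves only the BOS edge, not the COM
  seg2 <- de_leva_segments()
  seg2$proximal[seg2$segment == "foot_l"] <- list("LANK")
  seg2$proximal[seg2$segment == "foot_r"] <- list("RANK")
  com2 <- whole_body_com(mk, seg2)
  mk2 <- mk
  mk2$LHEE_y <- com2$com_y          # heel directly under the COM -> 0
  mk2$RHEE_y <- com2$com_y + 0.01
  expect_equal(com_bos_distance(mk2, 0.02, segments = seg2), 0,
               tolerance = 1e-9)
  mk3 <- mk
  mk3$LHEE_y <- com2$com_y + 0.023  # COM 23 mm behind the heel line
  mk3$RHEE_y <- com2$com_y + 0.04
  expect_equal(com_bos_distance(mk3, 0.02, segments = seg2), -0.023,
               tolerance = 1e-9)
})

test_that("deepest trunk flexion is the per-cycle maximum", {
  t <- seq(0, 2, by = 0.01)
  ang <- tibble::tibble(time_s = t, angle_deg = 10)
  cw <- tibble::tibble(cycle = 1L, start_s = 0, end_s = 2)
  expect_equal(deepest_trunk_flexion(ang, cw)$deepest_deg, 10)

  ang2 <- tibble::tibble(time_s = t, angle_deg = 41 * sin(pi * t / 2))
  out <- deepest_trunk_flexion(ang2, cw)
  expect_equal(out$deepest_deg, max(ang2$angle_deg))
  expect_equal(out$t_peak_s, t[which.max(ang2$angle_deg)])
})
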