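# Landmark-anchored areas of interest (AOI). The analysis plane is the
# body's sagittal viewing plane: the longitudinal coordinate is the
# laboratory vertical (z) position of the gaze point on the body, the
# transverse coordinate is lateral. Six bands -- head, neck, trunk, hip,
# knee, foot -- are bounded by landmark levels recomputed every frame.

#' AOI names in longitudinal order
#' @return character vector, head first.
#' @export
aoi_names <- function() c("head", "neck", "trunk", "hip", "knee", "foot")

#' Build the time-varying AOI layout from marker landmarks
#'
#' Band boundaries per frame (longitudinal coordinate, metres):
#' head = above the chin (head-marker centroid minus `chin_offset_m` along
#' the trunk axis); neck = chin down to the acromion line; trunk = upper 50%
#' of the acromion-to-hip span; hip = hip line down to mid-thigh; knee =
#' mid-thigh down to mid-shank; foot = below the lateral malleolus. The
#' mid-shank-to-malleolus strip and everything below the feet belong to no
#' AOI. Bands are half-open `[lower, upper)`; the head band is closed at the
#' top (unbounded), so every boundary point belongs to the upper band's
#' lower neighbour exactly once and the bands are pairwise disjoint.
#'
#' @param markers marker tibble.
#' @param chin_offset_m chin position below the head-marker centroid,
#'   measured along the trunk longitudinal axis (default 0.12 m).
#' @return tibble `time_s` plus boundary columns `b_chin`, `b_acromion`,
#'   `b_trunk_lo`, `b_midthigh`, `b_midshank`, `b_malleolus`, `b_foot_lo`;
#'   frames with missing landmarks are flagged in `valid`.
#' @export
build_aoi_layout <- function(markers, chin_offset_m = 0.12) {
  g <- function(m, ax) markers[[paste0(m, "_", ax)]]
  head_z <- (g("LFHD", "z") + g("RFHD", "z") + g("LBHD", "z") +
               g("RBHD", "z")) / 4
  sho_z <- (g("LSHO", "z") + g("RSHO", "z")) / 2
  hip_z <- (g("LHIP", "z") + g("RHIP", "z")) / 2
  kne_z <- (g("LKNE", "z") + g("RKNE", "z")) / 2
  ank_z <- (g("LANK", "z") + g("RANK", "z")) / 2
  foot_lo <- pmin(g("LHEE", "z"), g("RHEE", "z"),
                  g("LTOE", "z"), g("RTOE", "z")) - 0.02

  # trunk longitudinal direction for the chin offset
  upper <- cbind((g("CLAV", "x") + g("T2", "x")) / 2,
                 (g("CLAV", "y") + g("T2", "y")) / 2,
                 (g("CLAV", "z") + g("T2", "z")) / 2)
  lower <- cbind((g("STRN", "x") + g("T7", "x")) / 2,
                 (g("STRN", "y") + g("T7", "y")) / 2,
                 (g("STRN", "z") + g("T7", "z")) / 2)
  ax <- upper - lower
  axz <- ax[, 3] / sqrt(rowSums(ax^2))
  chin <- head_z - chin_offset_m * axz

  out <- tibble::tibble(
    time_s = markers$time_s %||% seq_len(nrow(markers)),
    b_chin = chin,
    b_acromion = sho_z,
    b_trunk_lo = (sho_z + hip_z) / 2,
    b_hip = hip_z,
    b_midthigh = (hip_z + kne_z) / 2,
    b_midshank = (kne_z + ank_z) / 2,
    b_malleolus = ank_z,
    b_foot_lo = foot_lo)
  bcols <- setdiff(names(out), "time_s")
  out$valid <- stats::complete.cases(out[bcols])
  class(out) <- c("sg_aoi_layout", class(out))
  out
}

# Band intervals [lower, upper) for one row of the layout; head unbounded.
.sg_band_bounds <- function(row) {
  list(
    head = c(row$b_chin, Inf),
    neck = c(row$b_acromion, row$b_chin),
    trunk = c(row$b_trunk_lo, row$b_acromion),
    hip = c(row$b_midthigh, row$b_trunk_lo),
    knee = c(row$b_midshank, row$b_midthigh),
    foot = c(row$b_foot_lo, row$b_malleolus))
}

#' Classify gaze points into AOI bands
#'
#' Assigns each (time, longitudinal-coordinate) gaze point to the AOI band
#' active at that time (boundaries linearly interpolated between frames).
#' Points in no band -- the lower-shank strip, below the feet, or frames
#' with unresolvable landmarks -- get `NA`.
#'
#' @param layout an [build_aoi_layout()] result.
#' @param time_s,v numeric vectors: query times and longitudinal positions.
#' @return character vector of AOI labels (or `NA`).
#' @export
classify_aoi <- function(layout, time_s, v) {
  b <- function(col) stats::approx(layout$time_s, layout[[col]],
                                   xout = time_s, rule = 2)$y
  chin <- b("b_chin"); acr <- b("b_acromion"); tlo <- b("b_trunk_lo")
  mth <- b("b_midthigh"); msh <- b("b_midshank"); mal <- b("b_malleolus")
  flo <- b("b_foot_lo")
  valid_t <- stats::approx(layout$time_s, as.numeric(layout$valid),
                           xout = time_s, rule = 2)$y >= 1
  lab <- rep(NA_character_, length(v))
  lab[v >= chin] <- "head"
  lab[v >= acr & v < chin] <- "neck"
  lab[v >= tlo & v < acr] <- "trunk"
  lab[v >= mth & v < tlo] <- "hip"
  lab[v >= msh & v < mth] <- "knee"
  lab[v >= flo & v < mal] <- "foot"
  lab[!valid_t] <- NA_character_
  lab
}

# Band centres used by the gaze generator to place fixations.
.sg_band_centres <- function(layout, time_s) {
  b <- function(col) stats::approx(layout$time_s, layout[[col]],
                                   xout = time_s, rule = 2)$y
  chin <- b("b_chin")
  tibble::tibble(
    head = chin + 0.10,
    neck = (b("b_acromion") + chin) / 2,
    trunk = (b("b_trunk_lo") + b("b_acromion")) / 2,
    hip = (b("b_midthigh") + b("b_trunk_lo")) / 2,
    knee = (b("b_midshank") + b("b_midthigh")) / 2,
    foot = (b("b_foot_lo") + b("b_malleolus")) / 2,
    off = (b("b_malleolus") + b("b_midshank")) / 2)
}

# Half-widths of each band (for jitter that stays inside the band).
.sg_band_halfwidth <- function(layout, time_s) {
  b <- function(col) stats::approx(layout$time_s, layout[[col]],
                                   xout = time_s, rule = 2)$y
  chin <- b("b_chin")
  tibble::tibble(
    head = 0.05,
    neck = (chin - b("b_acromion")) / 2,
    trunk = (b("b_acromion") - b("b_trunk_lo")) / 2,
    hip = (b("b_trunk_lo") - b("b_midthigh")) / 2,
    knee = (b("b_midthigh") - b("b_midshank")) / 2,
    foot = (b("b_malleolus") - b("b_foot_lo")) / 2,
    off = (b("b_midshank") - b("b_malleolus")) / 2)
}


# Vectorised [lower, upper] placement interval of one band per query time;
# the head band gets a finite ceiling for placement purposes.
.sg_band_interval <- function(layout, time_s, aoi) {
  b <- function(col) stats::approx(layout$time_s, layout[[col]],
                                   xout = time_s, rule = 2)$y
  switch(aoi,
    head = list(lo = b("b_chin"), hi = b("b_chin") + 0.22),
    neck = list(lo = b("b_acromion"), hi = b("b_chin")),
    trunk = list(lo = b("b_trunk_lo"), hi = b("b_acromion")),
    hip = list(lo = b("b_midthigh"), hi = b("b_trunk_lo")),
    knee = list(lo = b("b_midshank"), hi = b("b_midthigh")),
    foot = list(lo = b("b_foot_lo"), hi = b("b_malleolus")),
    off = list(lo = b("b_malleolus"), hi = b("b_midshank")))
}
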