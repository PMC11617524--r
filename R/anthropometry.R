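#' Canonical marker set
#'
#' Names of the 34 body markers plus the 3 sacral-jig markers used throughout
#' the package, loosely following the Plug-in-Gait naming convention. The jig
#' markers (`SJ1`-`SJ3`) sit on a rigid sacral cluster and are used to
#' reconstruct the anterior superior iliac spine (ASIS) markers when the
#' forward-bent torso occludes them.
#'
#' @return character vector of 37 marker names.
#' @export
marker_set <- function() {
  c("LFHD", "RFHD", "LBHD", "RBHD",
    "CLAV", "STRN", "T2", "T7",
    "LSHO", "RSHO", "LELB", "RELB", "LWRI", "RWRI",
    "LASI", "RASI", "LPSI", "RPSI",
    "LHIP", "RHIP", "LTHI", "RTHI", "LKNE", "RKNE",
    "LTIB", "RTIB", "LANK", "RANK",
    "LHEE", "RHEE", "LTOE", "RTOE", "LMT5", "RMT5",
    "SJ1", "SJ2", "SJ3")
}

#' Body segment parameter table
#'
#' Ten-segment division of the body (trunk, pelvis, left/right upper limb,
#' thigh, lower leg, foot) with per-segment mass fractions and the position of
#' the segment centre of mass as a fraction of the proximal-to-distal axis.
#' Fractions follow de Leva's (1996) adjustment of the Zatsiorsky tables for
#' adult males, with the head-and-neck mass folded into the trunk segment
#' (the ten-segment model carries no separate head segment, so the trunk COM
#' fraction is shifted proximally to account for the head above the
#' shoulders). Mass fractions sum to 1.
#'
#' Each segment's endpoints are resolved as the centroid of the listed marker
#' names, so the same table drives both the synthetic generator and the
#' analysis pipeline.
#'
#' @return tibble with columns `segment`, `proximal` (list of marker names),
#'   `distal`, `mass_frac`, `com_frac`.
#' @export
#' @examples
#' sum(de_leva_segments()$mass_frac)
de_leva_segments <- function() {
  tibble::tibble(
    segment = c("trunk", "pelvis",
                "arm_l", "arm_r", "thigh_l", "thigh_r",
                "shank_l", "shank_r", "foot_l", "foot_r"),
    proximal = list(c("LSHO", "RSHO"), c("LASI", "RASI"),
                    "LSHO", "RSHO", "LHIP", "RHIP",
                    "LKNE", "RKNE", "LHEE", "RHEE"),
    distal = list(c("LHIP", "RHIP"), c("LPSI", "RPSI"),
                  "LWRI", "RWRI", "LKNE", "RKNE",
                  "LANK", "RANK", "LTOE", "RTOE"),
    mass_frac = c(0.3923, 0.1117,
                  0.0494, 0.0494, 0.1416, 0.1416,
                  0.0433, 0.0433, 0.0137, 0.0137),
    com_frac = c(0.31, 0.50,
                 0.45, 0.45, 0.4095, 0.4095,
                 0.4459, 0.4459, 0.50, 0.50)
  )
}

validate_segments <- function(segments) {
  abort_if(abs(sum(segments$mass_frac) - 1) > 1e-6,
           "segment mass fractions must sum to 1 over the whole body")
  abort_if(any(segments$mass_frac <= 0), "segment mass fractions must be > 0")
  abort_if(any(segments$com_frac < 0 | segments$com_frac > 1),
           "segment COM fractions must lie in [0, 1]")
  invisible(segments)
}

#' Default articulated skeleton
#'
#' Segment lengths and marker offsets for the planar (sagittal) articulated
#' model used by the synthetic generator. Lengths scale linearly with stature.
#' The laboratory frame is x lateral-right, y forward (+), z up; all lengths
#' in metres.
#'
#' @param mass_kg collaborator body mass (kg), default 60.
#' @param stature_m collaborator stature (m), default 1.65.
#' @return object of class `sg_skeleton`.
#' @export
default_skeleton <- function(mass_kg = 60, stature_m = 1.65) {
  abort_if(!is.numeric(mass_kg) || mass_kg <= 0, "body mass must be > 0 kg")
  abort_if(!is.numeric(stature_m) || stature_m <= 0, "stature must be > 0 m")
  s <- stature_m / 1.65
  structure(list(
    mass_kg = mass_kg,
    stature_m = stature_m,
    shank_len = 0.41 * s,
    thigh_len = 0.40 * s,
    trunk_len = 0.50 * s,      # mid-hip to mid-shoulder
    head_off = 0.17 * s,       # shoulder line to head-marker centroid
    ankle_h = 0.075 * s,
    hip_halfwidth = 0.09,
    shoulder_halfwidth = 0.18,
    foot = list(heel_y = -0.06, toe_y = 0.16, mt5_y = 0.12,
                ank_x = 0.10, heel_z = 0.03, toe_z = 0.02)
  ), class = "sg_skeleton")
}

#' @export
print.sg_skeleton <- function(x, ...) {
  cat(sprintf("<sg_skeleton> mass %.1f kg, stature %.2f m, 37 markers\n",
              x$mass_kg, x$stature_m))
  invisible(x)
}
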