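# Segment orientations: Cardan angle decomposition, trunk flexion, ankle
# dorsiflexion. Convention: lab frame x lateral-right, y forward, z up;
# rotations about x are anterior-posterior tilt (flexion positive forward).

#' Cardan (X-Y-Z) angles of a rotation matrix
#'
#' Decomposes a rotation matrix `R` (segment-to-lab) as
#' `R = Rx(a) %*% Ry(b) %*% Rz(c)` and returns `c(a, b, c)` in degrees.
#' The x-component is the anterior-posterior tilt (flexion/extension).
#'
#' @param R 3x3 rotation matrix.
#' @return numeric vector `c(x = a, y = b, z = c)` in degrees.
#' @export
#' @examples
#' cardan_xyz(rotation_x(30))
cardan_xyz <- function(R) {
  b <- asin(pmin(pmax(R[1, 3], -1), 1))
  a <- atan2(-R[2, 3], R[3, 3])
  cc <- atan2(-R[1, 2], R[1, 1])
  c(x = a, y = b, z = cc) * 180 / pi
}

#' Elementary rotation matrices
#'
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# Build per-frame trunk segment basis vectors from the four torso markers.
# Longitudinal axis: mid(CLAV, T2) -> mid(STRN, T7); anterior axis from the
# front/back marker pairs, orthogonalised.
.sg_trunk_basis <- function(markers) {
  g <- function(m) cbind(markers[[paste0(m, "_x")]],
                         markers[[paste0(m, "_y")]],
                         markers[[paste0(m, "_z")]])
  upper <- (g("CLAV") + g("T2")) / 2
  lower <- (g("STRN") + g("T7")) / 2
  zax <- normalize_rows(upper - lower)
  ant <- (g("CLAV") + g("STRN")) / 2 - (g("T2") + g("T7")) / 2
  ant <- ant - zax * rowSums(ant * zax)
  yax <- normalize_rows(ant)
  xax <- cross3_rows(yax, zax)
  list(x = xax, y = yax, z = zax)
}

#' Trunk flexion angle
#'
#' Orientation of the trunk segment about the laboratory x-axis, from the
#' X-Y-Z Cardan decomposition of the marker-built trunk frame. Forward lean
#' (anterior tilt) is positive. For a single frame the full three-angle
#' decomposition is available through [cardan_xyz()].
#'
#' @param markers marker tibble containing the trunk markers `CLAV`, `STRN`,
#'   `T2`, `T7`.
#' @return tibble `time_s`, `angle_deg`.
#' @export
trunk_angle <- function(markers) {
  need <- paste0(rep(c("CLAV", "STRN", "T2", "T7"), each = 3),
                 "_", c("x", "y", "z"))
  abort_if(!all(need %in% names(markers)),
           "trunk markers (CLAV, STRN, T2, T7) are required",
           class = "standgaze_landmark_error")
  basis <- .sg_trunk_basis(markers)
  # Cardan x-angle of R = [x' y' z']: a = atan2(-R[2,3], R[3,3]) with
  # R[,3] = z'. Forward lean tips z' toward +y, so flexion = atan2(zy, zz).
  angle <- atan2(basis$z[, 2], basis$z[, 3]) * 180 / pi
  tibble::tibble(time_s = markers$time_s %||% seq_len(nrow(markers)),
                 angle_deg = angle)
}

#' Ankle dorsiflexion angle
#'
#' Sagittal-plane angle between the shank axis (ankle to knee) and the foot
#' axis (heel to toe), expressed so that dorsiflexion (shank rotating toward
#' the dorsum of the foot) is positive and a vertical shank over a flat foot
#' reads 0 degrees. Averaged over the two sides.
#'
#' @param markers marker tibble.
#' @return tibble `time_s`, `angle_deg`.
#' @export
ankle_angle <- function(markers) {
  side <- function(pfx) {
    sy <- markers[[paste0(pfx, "KNE_y")]] - markers[[paste0(pfx, "ANK_y")]]
    sz <- markers[[paste0(pfx, "KNE_z")]] - markers[[paste0(pfx, "ANK_z")]]
    fy <- markers[[paste0(pfx, "TOE_y")]] - markers[[paste0(pfx, "HEE_y")]]
    fz <- markers[[paste0(pfx, "TOE_z")]] - markers[[paste0(pfx, "HEE_z")]]
    shank <- atan2(sy, sz)   # forward inclination of the shank
    foot <- atan2(fz, fy)    # pitch of the foot sole
    (shank + foot) * 180 / pi
  }
  tibble::tibble(time_s = markers$time_s %||% seq_len(nrow(markers)),
                 angle_deg = (side("L") + side("R")) / 2)
}
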