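# Coordinate systems and angular arithmetic.
#
# Conventions used throughout the package:
#   * azimuth in [-180, 180), 0 = straight ahead, positive toward the
#     listener's LEFT; elevation in [-90, 90], positive up.
#   * interaural-polar: lateral in [-90, 90], positive left; polar in
#     [-90, 270), 0 = front at eye level, 90 = overhead, 180 = behind.
#   * cartesian frame: x front, y left, z up (right-handed).
# Angles are degrees at every public interface; radians only inside.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into a half-open interval
#'
#' @param x numeric vector of angles in degrees.
#' @param lo lower (included) edge of the target interval; the interval is
#'   `[lo, lo + 360)`.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(x, lo = -180) {
  ((x - lo) %% 360) + lo
}

#' Construct spherical directions
#'
#' A direction on the unit sphere in the head-centred spherical convention:
#' azimuth positive toward the listener's left, elevation positive up.
#'
#' @param azimuth_deg azimuth in degrees, wrapped into `[-180, 180)`.
#' @param elevation_deg elevation in degrees, must lie in `[-90, 90]`.
#' @return a data.frame of class `dir_sph` with columns `azimuth_deg`,
#'   `elevation_deg`. Vectorised: one row per direction.
#' @examples
#' dir_sph(c(0, 45), c(0, 30))
#' @export
dir_sph <- function(azimuth_deg, elevation_deg) {
  stopifnot(is.numeric(azimuth_deg), is.numeric(elevation_deg))
  n <- max(length(azimuth_deg), length(elevation_deg))
  azimuth_deg <- rep_len(azimuth_deg, n)
  elevation_deg <- rep_len(elevation_deg, n)
  if (any(!is.finite(azimuth_deg)) || any(!is.finite(elevation_deg)))
    stop("directions must be finite")
  if (any(elevation_deg < -90 - 1e-9 | elevation_deg > 90 + 1e-9))
    stop("elevation_deg must lie in [-90, 90]")
  d <- data.frame(azimuth_deg = wrap_angle(azimuth_deg, -180),
                  elevation_deg = pmin(90, pmax(-90, elevation_deg)))
  class(d) <- c("dir_sph", "data.frame")
  d
}

#' Construct interaural-polar directions
#'
#' @param lateral_deg lateral angle in degrees, in `[-90, 90]`, positive left.
#' @param polar_deg polar angle in degrees, wrapped into `[-90, 270)`;
#'   0 = front at eye level, 90 = overhead, 180 = behind.
#' @return a data.frame of class `dir_ip` with columns `lateral_deg`,
#'   `polar_deg`.
#' @export
dir_ip <- function(lateral_deg, polar_deg) {
  stopifnot(is.numeric(lateral_deg), is.numeric(polar_deg))
  n <- max(length(lateral_deg), length(polar_deg))
  lateral_deg <- rep_len(lateral_deg, n)
  polar_deg <- rep_len(polar_deg, n)
  if (any(!is.finite(lateral_deg)) || any(!is.finite(polar_deg)))
    stop("directions must be finite")
  if (any(lateral_deg < -90 - 1e-9 | lateral_deg > 90 + 1e-9))
    stop("lateral_deg must lie in [-90, 90]")
  d <- data.frame(lateral_deg = pmin(90, pmax(-90, lateral_deg)),
                  polar_deg = wrap_angle(polar_deg, -90))
  class(d) <- c("dir_ip", "data.frame")
  d
}

#' Spherical direction to cartesian unit vector
#'
#' @param d a `dir_sph` object (or data.frame with its columns).
#' @return an n x 3 matrix of unit vectors, columns x (front), y (left),
#'   z (up).
#' @export
sph_to_cart <- function(d) {
  az <- deg2rad(d$azimuth_deg)
  el <- deg2rad(d$elevation_deg)
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

#' Cartesian unit vectors to spherical directions
#'
#' @param v an n x 3 matrix (rows need not be exactly unit norm; they are
#'   normalised).
#' @return a `dir_sph` object.
#' @export
cart_to_sph <- function(v) {
  v <- matrix(v, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("zero-length vector has no direction")
  v <- v / nrm
  dir_sph(rad2deg(atan2(v[, 2], v[, 1])),
          rad2deg(asin(pmin(1, pmax(-1, v[, 3])))))
}

#' Spherical to interaural-polar coordinates
#'
#' With unit vector (x front, y left, z up): lateral = asin(y),
#' polar = atan2(z, x), polar wrapped to `[-90, 270)`.
#'
#' @param d a `dir_sph` object.
#' @return a `dir_ip` object.
#' @examples
#' sph_to_interaural(dir_sph(45, 30))
#' @export
sph_to_interaural <- function(d) {
  v <- sph_to_cart(d)
  lat <- rad2deg(asin(pmin(1, pmax(-1, v[, 2]))))
  pol <- rad2deg(atan2(v[, 3], v[, 1]))
  # at the interaural poles (|lateral| = 90) the polar angle is undefined;
  # atan2(0, 0) = 0 is a stable canonical choice
  dir_ip(lat, wrap_angle(pol, -90))
}

#' Interaural-polar to spherical coordinates
#'
#' Exact inverse of [sph_to_interaural()].
#'
#' @param d a `dir_ip` object.
#' @return a `dir_sph` object.
#' @export
interaural_to_sph <- function(d) {
  lat <- deg2rad(d$lateral_deg)
  pol <- deg2rad(d$polar_deg)
  v <- cbind(cos(lat) * cos(pol), sin(lat), cos(lat) * sin(pol))
  cart_to_sph(v)
}

#' Construct a head orientation
#'
#' Rotation applied in yaw -> pitch -> roll order about body axes
#' (z up, y left, x front). Positive yaw turns the head toward the left
#' (matching positive azimuth); positive pitch tilts the head up; roll is
#' carried for completeness but unused by the experiment generators.
#'
#' @param yaw_deg,pitch_deg,roll_deg rotation angles in degrees.
#' @return a data.frame of class `head_orientation`.
#' @export
head_orientation <- function(yaw_deg = 0, pitch_deg = 0, roll_deg = 0) {
  n <- max(length(yaw_deg), length(pitch_deg), length(roll_deg))
  o <- data.frame(yaw_deg = rep_len(yaw_deg, n),
                  pitch_deg = rep_len(pitch_deg, n),
                  roll_deg = rep_len(roll_deg, n))
  if (any(!is.finite(as.matrix(o)))) stop("orientation angles must be finite")
  class(o) <- c("head_orientation", "data.frame")
  o
}

# 3x3 rotation matrix for one head orientation (world-from-head).
# Columns are the head's front/left/up axes expressed in world coordinates.
orientation_matrix <- function(yaw_deg, pitch_deg, roll_deg = 0) {
  cy <- cos(deg2rad(yaw_deg));  sy <- sin(deg2rad(yaw_deg))
  cp <- cos(deg2rad(pitch_deg)); sp <- sin(deg2rad(pitch_deg))
  cr <- cos(deg2rad(roll_deg)); sr <- sin(deg2rad(roll_deg))
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)       # yaw, +left
  Ry <- matrix(c(cp, 0, sp, 0, 1, 0, -sp, 0, cp), 3, 3)       # pitch, +up
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)       # roll
  Rz %*% Ry %*% Rx
}

#' Source direction in the rotated head frame
#'
#' Expresses a world-fixed source direction in the coordinate frame of a
#' rotated head (the inverse head rotation applied to the source vector).
#' This is the direction the renderer must look up in the HRTF set.
#'
#' @param d a `dir_sph` source direction (world frame). One row, or as many
#'   rows as `o`.
#' @param o a `head_orientation` (one row per evaluation).
#' @return a `dir_sph` object of head-relative directions.
#' @examples
#' head_relative_direction(dir_sph(10, 0), head_orientation(yaw_deg = 10))
#' @export
head_relative_direction <- function(d, o) {
  n <- max(nrow(d), nrow(o))
  v <- sph_to_cart(d)
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  oy <- rep_len(o$yaw_deg, n); op <- rep_len(o$pitch_deg, n)
  or <- rep_len(o$roll_deg, n)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- orientation_matrix(oy[i], op[i], or[i])
    out[i, ] <- drop(t(R) %*% v[i, ])
  }
  cart_to_sph(out)
}

#' Great-circle angle between two directions
#'
#' @param d1,d2 `dir_sph` objects (recycled to a common length).
#' @return angle(s) in degrees, in `[0, 180]`.
#' @examples
#' angular_distance(dir_sph(0, 0), dir_sph(90, 45))
#' @export
angular_distance <- function(d1, d2) {
  v1 <- sph_to_cart(d1)
  v2 <- sph_to_cart(d2)
  n <- max(nrow(v1), nrow(v2))
  if (nrow(v1) == 1L) v1 <- v1[rep(1L, n), , drop = FALSE]
  if (nrow(v2) == 1L) v2 <- v2[rep(1L, n), , drop = FALSE]
  # atan2(|cross|, dot) resolves small angles far below the acos floor
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  unname(rad2deg(atan2(sqrt(cx^2 + cy^2 + cz^2), rowSums(v1 * v2))))
}
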