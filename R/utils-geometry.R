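# Small 3-vector helpers shared by the frame and corridor code.
# All coordinates are millimetres in the scanner frame, right-handed.

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps^0.5)
    stop("cannot normalise a (near-)zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dot3 <- function(a, b) sum(a * b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotate a vector about an axis (Rodrigues formula)
#'
#' @param x numeric 3-vector to rotate.
#' @param axis rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees, right-hand rule about `axis`.
#' @return the rotated 3-vector.
#' @keywords internal
rotate_about <- function(x, axis, angle_deg) {
  k <- unitv(axis)
  th <- deg2rad(angle_deg)
  x * cos(th) + cross3(k, x) * sin(th) + k * dot3(k, x) * (1 - cos(th))
}

# 3x3 rotation matrix about an axis, for transforming point sets.
rotation_matrix <- function(axis, angle_deg) {
  k <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle between two vectors in degrees, clamped for FP safety.
angle_between_deg <- function(a, b) {
  ca <- dot3(unitv(a), unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# A deterministic orthonormal basis (u, v) of the plane normal to d:
# u is built from the coordinate axis least aligned with d, so that the
# basis varies smoothly for nearby directions in the azimuth scan.
plane_basis <- function(d) {
  d <- unitv(d)
  e <- diag(3)[, which.min(abs(d))]
  u <- unitv(cross3(e, d))
  v <- cross3(d, u)
  list(u = u, v = v)
}
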