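# 3D geometry primitives: torsion measurement and NeRF atom placement.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v * v))

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 axis, a clockwise rotation
#' of p4 relative to p1 is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place atom D from reference atoms A, B, C with bond length |C-D|, bond
# angle B-C-D (deg) and torsion A-B-C-D (deg). Natural extension reference
# frame; exact up to floating point, so rebuilt conformations are
# bit-reproducible for identical inputs.
nerf_place <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # frame handedness: measured IUPAC torsion equals `torsion`
  bc <- .unit(c_ - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix from a unit quaternion (used by fixture generators)
.quat_rotation <- function(q) {
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
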