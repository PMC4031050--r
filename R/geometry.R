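# Low-level vector / rotation / internal-coordinate primitives shared by the
# helix geometry, sampler and loop building code.  All angles at this level
# are in degrees unless a name says otherwise; coordinates are Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees to the interval (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Rotation matrix for a right-handed rotation of `theta_deg` degrees about
# the (not necessarily unit) axis vector.
rot_axis_angle <- function(axis, theta_deg) {
  u <- unitv(axis)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) + st * K + (1 - ct) * (K %*% K)
}

# Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  ax <- vcross(a, b)
  s <- vnorm(ax)
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3L))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    p <- vcross(a, c(1, 0, 0))
    if (vnorm(p) < 1e-6) p <- vcross(a, c(0, 1, 0))
    return(rot_axis_angle(p, 180))
  }
  rot_axis_angle(ax, rad2deg(atan2(s, d)))
}

# Angle (degrees) at b formed by a-b-c.
angle3 <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion angle of four points
#'
#' Signed dihedral p1-p2-p3-p4 in degrees, IUPAC sign convention.
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(-rad2deg(atan2(y, x)))
}

# Vectorized dihedral over rows of four point matrices.
batch_dihedral <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  n1 <- cbind(b1[, 2L] * b2[, 3L] - b1[, 3L] * b2[, 2L],
              b1[, 3L] * b2[, 1L] - b1[, 1L] * b2[, 3L],
              b1[, 1L] * b2[, 2L] - b1[, 2L] * b2[, 1L])
  n2 <- cbind(b2[, 2L] * b3[, 3L] - b2[, 3L] * b3[, 2L],
              b2[, 3L] * b3[, 1L] - b2[, 1L] * b3[, 3L],
              b2[, 1L] * b3[, 2L] - b2[, 2L] * b3[, 1L])
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cbind(n1[, 2L] * b2n[, 3L] - n1[, 3L] * b2n[, 2L],
              n1[, 3L] * b2n[, 1L] - n1[, 1L] * b2n[, 3L],
              n1[, 1L] * b2n[, 2L] - n1[, 2L] * b2n[, 1L])
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  wrap_angle(-rad2deg(atan2(y, x)))
}

# NeRF atom placement: position atom D given the three preceding atoms A-B-C,
# the C-D bond length, the B-C-D bond angle and the A-B-C-D torsion.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)                     # bc, m, n: right-handed frame
  ang <- deg2rad(180 - angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- bond * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Apply rotation R (3x3) about pivot then translate by t to an n x 3 matrix.
transform_xyz <- function(xyz, R = NULL, t = c(0, 0, 0),
                          pivot = c(0, 0, 0)) {
  if (is.null(xyz) || nrow(xyz) == 0L) return(xyz)
  x <- xyz[, 1L] - pivot[1L]
  y <- xyz[, 2L] - pivot[2L]
  z <- xyz[, 3L] - pivot[3L]
  if (is.null(R)) {
    out <- cbind(x + pivot[1L] + t[1L], y + pivot[2L] + t[2L],
                 z + pivot[3L] + t[3L], deparse.level = 0L)
  } else {
    out <- cbind(
      R[1L, 1L] * x + R[1L, 2L] * y + R[1L, 3L] * z + pivot[1L] + t[1L],
      R[2L, 1L] * x + R[2L, 2L] * y + R[2L, 3L] * z + pivot[2L] + t[2L],
      R[3L, 1L] * x + R[3L, 2L] * y + R[3L, 3L] * z + pivot[3L] + t[3L],
      deparse.level = 0L)
  }
  out
}
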