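# Low-level vector geometry shared by the builders and the metrics.
# All vectors are plain numeric length-3; all angles are degrees unless the
# function name says otherwise.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v^2))

vhat <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors in degrees
#' @noRd
vangle <- function(a, b) {
  ca <- sum(vhat(a) * vhat(b))
  acos(pmin(1, pmax(-1, ca))) / DEG
}

#' Rotation matrix about an arbitrary axis (Rodrigues), angle in degrees
#' @noRd
rotation_about <- function(axis, angle_deg) {
  u <- vhat(axis)
  th <- angle_deg * DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation taking unit vector `from` onto unit vector `to`
#' @noRd
rotation_between <- function(from, to) {
  f <- vhat(from); t <- vhat(to)
  ax <- vcross(f, t)
  s <- vnorm(ax)
  if (s < 1e-12) {
    if (sum(f * t) > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about(vcross(f, p), 180))
  }
  rotation_about(ax, atan2(s, sum(f * t)) / DEG)
}

#' Planar angle at vertex b (degrees, [0, 180])
#' @noRd
planar_angle <- function(a, b, c) vangle(a - b, c - b)

#' Dihedral angle for points a-b-c-d, degrees in (-180, 180]
#'
#' Sign follows the IUPAC convention: looking from b to c, a positive angle
#' is a clockwise rotation of the a-projection onto the d-projection.
#' @noRd
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vhat(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -atan2(y, x) / DEG
}

#' Map an angle in degrees onto [0, 360)
#' @noRd
wrap360 <- function(a) ((a %% 360) + 360) %% 360

#' Place a new atom by internal coordinates (NeRF)
#'
#' Given positions a, b, c, returns the point d such that |c-d| = bond,
#' angle(b, c, d) = angle_deg and dihedral(a, b, c, d) = torsion_deg.
#' @noRd
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * DEG
  ph <- torsion_deg * DEG
  bc <- vhat(c - b)
  n <- vhat(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Minimum inter-set heavy atom distance
#' @noRd
min_pair_distance <- function(xyz_a, xyz_b) {
  sqrt(max(0, min(cross_dist2(xyz_a, xyz_b))))
}

#' Squared distance matrix between two coordinate matrices (n x 3, m x 3)
#' @noRd
cross_dist2 <- function(xyz_a, xyz_b) {
  a2 <- rowSums(xyz_a^2)
  b2 <- rowSums(xyz_b^2)
  d2 <- outer(a2, b2, "+") - 2 * xyz_a %*% t(xyz_b)
  d2[d2 < 0] <- 0
  d2
}
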