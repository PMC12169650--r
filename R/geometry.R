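# Low-level vector/rotation utilities shared by all geometry modules.
# Angles are radians internally; user-facing functions convert to degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near) zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about unit axis u by angle a (radians)
rot_axis <- function(u, a) {
  u <- unitv(u)
  ca <- cos(a); sa <- sin(a)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ca + sa * ux + (1 - ca) * (u %o% u)
}

# Signed angle from a to b about axis (radians, in (-pi, pi])
signed_angle <- function(a, b, axis) {
  atan2(sum(cross3(a, b) * axis), sum(a * b))
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle p1-p2-p3-p4 with the IUPAC sign convention:
#' looking from p2 to p3, a clockwise rotation of p4 relative to p1 is
#' positive. Returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return Torsion angle in degrees.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("dihedral: coincident points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("dihedral: collinear points")
  ang <- atan2(sum(cross3(n1, n2) * unitv(b2)), sum(n1 * n2))
  ang <- rad2deg(ang)
  if (ang <= -180) ang <- ang + 360
  ang
}

# Kabsch optimal proper rotation mapping `from` onto `to` (n x 3 matrices,
# rows are matched atoms). Returns list(R, t) with to ~ from %*% t(R) + t.
kabsch_fit <- function(from, to) {
  if (nrow(from) < 3) stop("kabsch_fit: need at least 3 matched atoms")
  cf <- colMeans(from)
  ct <- colMeans(to)
  A <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(ct - R %*% cf))
}

# Orientation frame: right-handed orthonormal rotation + origin.
new_frame <- function(R = diag(3), o = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(o) == 3)
  list(R = R, o = as.numeric(o))
}

is_proper_rotation <- function(R, tol = 1e-9) {
  abs(det(R) - 1) < tol && max(abs(t(R) %*% R - diag(3))) < tol
}

# flip a base frame 180 degrees about its own x axis (Crick-strand convention)
flip_frame <- function(f) {
  new_frame(f$R %*% diag(c(1, -1, -1)), f$o)
}
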