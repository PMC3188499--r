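# Small 3D geometry kernel used by the internal-coordinate builders and the
# torsion kinematics. All angles are in degrees at the API surface.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle defined by three points
#'
#' @param a,b,c numeric 3-vectors; the angle is measured at `b`.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
pointAngle <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle defined by four points
#'
#' Signed torsion a-b-c-d about the b-c axis, IUPAC convention
#' (cis = 0, looking from b to c a clockwise rotation of d is positive).
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral in degrees in (-180, 180\].
#' @keywords internal
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -.rad2deg(atan2(y, x))
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given reference positions `a`, `b`, `c`, returns the position `d` with
#' bond length |c-d| = `bond`, angle b-c-d = `angle` and dihedral
#' a-b-c-d = `torsion`.
#'
#' @param a,b,c numeric 3-vectors (must not be collinear).
#' @param bond bond length in Angstrom (> 0).
#' @param angle bond angle in degrees.
#' @param torsion dihedral in degrees.
#' @return numeric 3-vector.
#' @keywords internal
placeAtom <- function(a, b, c, bond, angle, torsion) {
  stopifnot(bond > 0)
  th <- .deg2rad(angle)
  ph <- .deg2rad(torsion)
  bc <- .unit(c - b)
  n <- .cross(b - a, bc)
  if (.vnorm(n) < 1e-10)
    stop("collinear reference atoms in placeAtom")
  n <- .unit(n)
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rodrigues rotation matrix for a unit axis and angle in radians.
.rotationMatrix <- function(axis, theta) {
  u <- .unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Rotate rows of xyz[idx, ] by `deg` degrees about the axis through point
# `origin` with direction `axis`.
.rotateAbout <- function(xyz, idx, origin, axis, deg) {
  if (length(idx) == 0 || abs(deg) < 1e-15) return(xyz)
  R <- .rotationMatrix(axis, .deg2rad(deg))
  sub <- sweep(xyz[idx, , drop = FALSE], 2, origin)
  xyz[idx, ] <- sweep(sub %*% t(R), 2, origin, `+`)
  xyz
}
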