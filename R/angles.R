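# Elementary 3D vector algebra shared by the torsion, hydrogen-bond and
# ring-current geometry code.  All angles are in degrees, all distances in
# Angstrom, torsions follow the right-hand IUPAC convention and live in
# [-180, 180).

DEG <- 180 / pi

vdot <- function(a, b) sum(a * b)

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Wrap an angle into [-180, 180)
#'
#' Canonical representation used for every torsion-like quantity in the
#' package: 180 maps to -180, so each physical angle has exactly one
#' representative.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in `[-180, 180)`.
#' @examples
#' wrap_angle(c(180, -190, 725))  # -> -180, 170, 5
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  ((x + 180) %% 360) - 180
}

#' Angle at the middle point of three positions
#'
#' @param p1,p2,p3 Cartesian triples; the angle is measured at `p2`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_at <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  d <- max(-1, min(1, vdot(u, v)))
  acos(d) * DEG
}

#' Signed torsion angle of four points
#'
#' Right-hand rule about the p2 -> p3 axis; a planar cis arrangement gives 0
#' and trans gives -180 (the [-180, 180) representative of 180).
#'
#' @param p1,p2,p3,p4 Cartesian triples (numeric length-3 vectors).
#' @return torsion in degrees in `[-180, 180)`.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b2) < 1e-9) stop("undefined torsion: p2 and p3 coincide")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: three consecutive points are collinear")
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(vdot(m1, n2), vdot(n1, n2)) * DEG
  wrap_angle(ang)
}

# Natural extension reference frame (NeRF) atom placement: returns the
# position D bonded to c such that |D - c| = bond, angle(D, c, b) = angle
# and dihedral(a, b, c, D) = torsion.  Used by the toy-structure builder
# and the amide-hydrogen construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
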