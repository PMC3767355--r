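#' Signed dihedral angle of four points
#'
#' Computes the torsion angle about the p2--p3 axis using the IUPAC sign
#' convention: looking from p2 towards p3, a clockwise rotation of the
#' far bond relative to the near bond is positive. 0 degrees is the
#' eclipsed (cis) arrangement and 180 degrees the anti (trans) one.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) # 0, cis
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # 180, trans
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    mc_stop("degenerate geometry: three consecutive points are collinear",
            "macroconf_degenerate_geometry")
  }
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares plane through a point cloud
#'
#' Fits the plane minimising the sum of squared point-plane distances
#' (total least squares, via the SVD of the centred coordinates).
#'
#' The normal sign is fixed by a convention: if `orient` is supplied the
#' normal is flipped to have a positive component along it (used by the
#' classifier, which orients site normals along the ring-centroid to
#' site-centroid vector); otherwise the largest-magnitude component of
#' the normal is made positive.
#'
#' @param points Numeric matrix, n x 3 with n >= 3.
#' @param orient Optional 3-vector fixing the normal sign.
#' @return List with `normal` (unit 3-vector), `centroid` (3-vector) and
#'   `rmsd` (root-mean-square point-plane distance).
#' @export
least_squares_plane <- function(points, orient = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    mc_stop("need at least 3 points to define a plane",
            "macroconf_degenerate_geometry")
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    mc_stop("degenerate geometry: points are collinear",
            "macroconf_degenerate_geometry")
  }
  n <- sv$v[, 3]
  n <- n / sqrt(sum(n^2))
  if (!is.null(orient)) {
    s <- sum(n * orient)
    if (s < 0) n <- -n
  } else {
    k <- which.max(abs(n))
    if (n[k] < 0) n <- -n
  }
  list(normal = n, centroid = ctr,
       rmsd = sqrt(mean((x %*% n)^2)))
}

#' Angle between two planes
#'
#' The mutual inclination of two planes from their unit normals,
#' `acos(|n1 . n2|)`; antiparallel normals describe the same plane
#' orientation, so the result is folded into \[0, 90\] degrees.
#'
#' @param n1,n2 Unit normal 3-vectors.
#' @return Angle in degrees in \[0, 90\].
#' @export
interplane_angle <- function(n1, n2) {
  l1 <- sqrt(sum(n1^2))
  l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) {
    mc_stop("zero-length normal vector", "macroconf_degenerate_geometry")
  }
  d <- abs(sum(n1 * n2) / (l1 * l2))
  acos(min(1, d)) * 180 / pi
}

# circular absolute difference of two angles in degrees, result in [0, 180]
circ_diff <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

#' Torsion-space distance between two conformers
#'
#' Maximum absolute circular difference over a list of torsion
#' quadruples; the deduplication pseudometric of the conformational
#' search.
#'
#' @param conf_a,conf_b N x 3 coordinate matrices of the same molecule.
#' @param torsions List of integer 4-vectors (atom indices).
#' @return Distance in degrees in \[0, 180\].
#' @export
torsion_distance <- function(conf_a, conf_b, torsions) {
  ta <- conformer_torsions(conf_a, torsions)
  tb <- conformer_torsions(conf_b, torsions)
  max(circ_diff(ta, tb))
}

conformer_torsions <- function(conf, torsions) {
  vapply(torsions, function(q) {
    dihedral_angle(conf[q[1], ], conf[q[2], ], conf[q[3], ], conf[q[4], ])
  }, numeric(1))
}

# Rodrigues rotation of points (n x 3) about unit axis through origin
rotate_about_axis <- function(points, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  pts <- as.matrix(points)
  kx <- pts %*% k
  crossed <- cbind(k[2] * pts[, 3] - k[3] * pts[, 2],
                   k[3] * pts[, 1] - k[1] * pts[, 3],
                   k[1] * pts[, 2] - k[2] * pts[, 1])
  pts * cos(th) + crossed * sin(th) +
    outer(as.vector(kx), k) * (1 - cos(th))
}

# random proper rotation matrix (used by tests and fixture generation)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}
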