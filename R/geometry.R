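# Small 3D geometry helpers shared by the fixture generators, the
# superposition code and the descriptor suite. Coordinates are plain
# numeric matrices with 3 columns (x, y, z), in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from an axis and an angle
#'
#' Rodrigues' formula. `axis` need not be normalised.
#'
#' @param axis numeric 3-vector, rotation axis.
#' @param angle rotation angle in radians.
#' @return a 3x3 proper rotation matrix.
#' @keywords internal
rotation_axis_angle <- function(axis, angle) {
  k <- unitv(axis)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Dihedral angle (degrees, IUPAC sign convention) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a fourth atom D given three positioned atoms A, B, C and the
# internal coordinates of D relative to them: bond length |C-D|, bond
# angle B-C-D (degrees) and torsion A-B-C-D (degrees). This is the NeRF
# construction used to grow idealized backbones.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral). Used by the Shrake-Rupley surface estimate; the point set is a
# pure function of n, so all surface quantities are deterministic.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Squared-distance matrix between the rows of two coordinate matrices.
cdist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- -2 * tcrossprod(a, b)
  d2 <- d2 + an                      # column-major recycling over rows
  d2 <- d2 + rep(bn, each = nrow(d2))
  d2[d2 < 0] <- 0
  d2
}

cdist <- function(a, b) sqrt(cdist2(a, b))
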