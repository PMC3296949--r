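# Internal 3D geometry helpers: vectors, dihedrals, NeRF atom placement,
# axis rotations and least-squares (Kabsch) superposition.  Coordinates are
# plain numeric length-3 vectors or n x 3 matrices, always in Angstrom.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## Reduce an angle in degrees to [0, 360)
.wrap360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  # guard against 360 - eps rounding back to exactly 360
  y[y >= 360] <- 0
  y
}

## Signed dihedral angle a-b-c-d in degrees, range (-180, 180].
## atan2 formulation, numerically stable away from colinear b-c geometries.
.dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("degenerate (colinear) dihedral quadruple")
  }
  m <- .cross3(n1, .unit(b2))
  -.rad2deg(atan2(sum(m * n2), sum(n1 * n2)))
}

## Dihedral reported on [0, 360)
.dihedral360 <- function(a, b, c, d) .wrap360(.dihedral(a, b, c, d))

## Natural extension of reference frame (NeRF): place atom D given atoms
## A, B, C, the C-D bond length, the B-C-D angle (deg) and the A-B-C-D
## dihedral (deg).
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- .deg2rad(angle)
  tor <- .deg2rad(dihedral)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d_local)
}

## Rotation matrix for a rotation by `angle_deg` about the axis through
## `origin` along unit vector of `axis` (Rodrigues).
.rotation_about_axis <- function(axis, angle_deg) {
  k <- .unit(axis)
  th <- .deg2rad(angle_deg)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), nrow = 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Rotate the rows of `coords` about the axis (origin, axis) by angle_deg.
.rotate_coords <- function(coords, origin, axis, angle_deg) {
  R <- .rotation_about_axis(axis, angle_deg)
  shifted <- sweep(coords, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, FUN = "+")
}

## Kabsch: optimal proper rigid transform mapping `mov` (n x 3) onto
## `ref` (n x 3) in the least-squares sense.  Returns rotation R,
## translation t (x_new = x %*% t(R) + t) and the residual rmsd.
.kabsch <- function(ref, mov) {
  ref <- as.matrix(ref)
  mov <- as.matrix(mov)
  stopifnot(nrow(ref) == nrow(mov), ncol(ref) == 3L, ncol(mov) == 3L)
  if (nrow(ref) < 3L) stop("superposition needs at least 3 points")
  cr <- colMeans(ref)
  cm <- colMeans(mov)
  P <- sweep(mov, 2L, cm)
  Q <- sweep(ref, 2L, cr)
  # colinearity guard: rank of the centred point cloud must be >= 2
  if (qr(P, tol = 1e-9)$rank < 2L || qr(Q, tol = 1e-9)$rank < 2L) {
    stop("degenerate (colinear) point sets cannot define a superposition")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- sweep(mov %*% t(R), 2L, t_vec, FUN = "+")
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  list(rotation = R, translation = t_vec, fit_rmsd = rmsd)
}

## Squared-distance matrix between two point sets (m x 3, n x 3) -> m x n.
.dist2_matrix <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Ideal C-beta position from backbone N, CA, C (used for glycine sites).
## Tetrahedral L-configuration: improper dihedral C-N-CA-CB = -122.5 deg.
.ideal_cb <- function(n, ca, c) {
  .place_atom(c, n, ca, bond = 1.53, angle = 110.5, dihedral = -122.5)
}
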