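# Shared oracles and small builders for the test suite.  Oracles are kept
# independent of the implementation paths they check: brute-force scans,
# bio3d reference routines, and hand-built geometries.

# O(n) brute-force radius query: indices of atoms with d <= r (closed ball).
brute_radius <- function(coords, point, r) {
  d2 <- (coords[, 1] - point[1])^2 + (coords[, 2] - point[2])^2 +
    (coords[, 3] - point[3])^2
  sort(which(d2 <= r * r))
}

# Brute-force clash/contact recount over an explicit env coordinate matrix.
brute_min_dists <- function(label_xyz, env_xyz) {
  apply(env_xyz, 1, function(p) {
    sqrt(min((label_xyz[, 1] - p[1])^2 + (label_xyz[, 2] - p[2])^2 +
               (label_xyz[, 3] - p[3])^2))
  })
}

# Smallest circular difference between two angle vectors, degrees.
circ_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Circular standard deviation in degrees.
circ_sd <- function(x) {
  th <- x * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(rbar)) * 180 / pi
}

# Independent dihedral oracle (bio3d); coords in the order a, b, c, d.
bio3d_dihedral <- function(a, b, c, d) {
  ang <- bio3d::torsion.xyz(c(a, b, c, d))
  (ang + 360) %% 360
}

# Coordinates of one conformer's clash-tested (side-chain) atoms.
side_chain_xyz <- function(cf) {
  cf$coords[cf$template$side_chain_names, , drop = FALSE]
}

# Environment coordinate matrix for a structure/site at default settings.
env_xyz_for <- function(s, st) {
  as.matrix(environment_for_site(s, st)[, c("x", "y", "z")])
}

# A minimal hand-written one-residue glycine PDB text (4 heavy atoms).
glycine_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.004   1.423   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.395   0.000  1.00  0.00           O",
    "END"), collapse = "\n")
}

# Random rigid transform (proper rotation + translation) under a seed.
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, 360)
  tr <- stats::rnorm(3, sd = 10)
  k <- ax / sqrt(sum(ax^2))
  th <- ang * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = tr,
       apply = function(xyz) sweep(xyz %*% t(R), 2, tr, FUN = "+"))
}

# Apply a rigid transform to a protein_structure's coordinates.
transform_structure <- function(s, rig) {
  xyz <- rig$apply(as.matrix(s$atoms[, c("x", "y", "z")]))
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# Shipped real structure (lysozyme) from the installed bio3d package.
lysozyme_path <- function() {
  system.file("examples", "1hel.pdb", package = "bio3d")
}
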