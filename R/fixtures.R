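# fixtures: programmatic synthetic structures, so every algorithm is
# testable without downloading anything.  The shapes emulate the
# situations a practitioner meets: a fully exposed surface site, a label
# seated in a cone-shaped cavity, a flat steric wall, a site sealed
# inside a cage, and an exactly symmetric dimer.
#
# Pseudo-atoms of walls, cones and cages are plain carbon ATOM records
# (residue DUM, chain Z, one atom per residue) so the uniform clash
# cutoff applies to them unchanged; their 1.5 A spacing makes barriers
# impervious at every sanctioned cutoff (>= 2.6 A).

.backbone_atom <- function(name, element, xyz, resno, resid, chain = "A") {
  data.frame(name = name, element = element,
             x = xyz[1L], y = xyz[2L], z = xyz[3L],
             resno = resno, ins = "", chain = chain, resid = resid,
             het = FALSE, hyd = FALSE, stringsAsFactors = FALSE)
}

## Extended (phi = psi = 180, omega = 180) backbone of `sequence`
## (3-letter codes); ALA residues get a C-beta.
.build_extended_peptide <- function(sequence, chain = "A") {
  rows <- list()
  prev <- NULL  # list(n, ca, c)
  for (i in seq_along(sequence)) {
    if (i == 1L) {
      n <- c(0, 0, 0)
      ca <- c(1.458, 0, 0)
      ang <- .deg2rad(180 - 111)
      cc <- ca + 1.525 * c(cos(ang), sin(ang), 0)
    } else {
      n <- .place_atom(prev$n, prev$ca, prev$c, 1.329, 116.2, 180)   # psi
      ca <- .place_atom(prev$ca, prev$c, n, 1.458, 121.7, 180)       # omega
      cc <- .place_atom(prev$c, n, ca, 1.525, 111.0, 180)            # phi
    }
    o <- .place_atom(n, ca, cc, 1.231, 120.5, 0)
    resid <- sequence[i]
    rows[[length(rows) + 1L]] <- .backbone_atom("N", "N", n, i, resid, chain)
    rows[[length(rows) + 1L]] <- .backbone_atom("CA", "C", ca, i, resid, chain)
    rows[[length(rows) + 1L]] <- .backbone_atom("C", "C", cc, i, resid, chain)
    rows[[length(rows) + 1L]] <- .backbone_atom("O", "O", o, i, resid, chain)
    if (resid != "GLY") {
      cb <- .place_atom(cc, n, ca, 1.53, 110.5, -122.5)
      rows[[length(rows) + 1L]] <- .backbone_atom("CB", "C", cb, i, resid, chain)
    }
    prev <- list(n = n, ca = ca, c = cc)
  }
  do.call(rbind, rows)
}

## Translate/rotate a fixture so the middle-residue CA sits at the origin
## and its CA -> CB direction points along +x (the direction the label
## side chain emanates).
.orient_on_site <- function(atoms, resno = 2L) {
  ca <- as.numeric(atoms[atoms$resno == resno & atoms$name == "CA",
                         c("x", "y", "z")])
  cb <- as.numeric(atoms[atoms$resno == resno & atoms$name == "CB",
                         c("x", "y", "z")])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2L, ca)
  v <- .unit(cb - ca)
  axis <- .cross3(v, c(1, 0, 0))
  if (sqrt(sum(axis^2)) > 1e-9) {
    ang <- .rad2deg(acos(max(-1, min(1, v[1L]))))
    R <- .rotation_about_axis(axis, ang)
    xyz <- xyz %*% t(R)
  }
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

.dummy_atoms <- function(xyz, start_resno = 100L, chain = "Z") {
  n <- nrow(xyz)
  data.frame(name = "C", element = "C",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             resno = start_resno + seq_len(n) - 1L, ins = "", chain = chain,
             resid = "DUM", het = FALSE, hyd = FALSE,
             stringsAsFactors = FALSE)
}

#' Exposed tripeptide fixture
#'
#' Extended Gly-Ala-Gly tripeptide with ideal backbone geometry; the
#' middle alanine is the labeling site and sees essentially no occlusion
#' beyond the two flanking residues, so a search accepts most trials.
#'
#' @return A `protein_structure` (chain A, residues 1-3).
#' @export
make_gxg_peptide <- function() {
  .new_structure(.build_extended_peptide(c("GLY", "ALA", "GLY")),
                 source_id = "gxg")
}

#' Cone-shaped cavity fixture
#'
#' The tripeptide site enclosed in a spherical shell of carbon
#' pseudo-atoms with a cone-shaped opening along the CA->CB axis: a label
#' at the bottom of a conical pit.  Only conformers threading the nitroxide
#' through the aperture survive the clash test, so a narrower aperture
#' leaves fewer accepted conformers and a narrower chi spread.
#'
#' @param aperture_deg Full opening angle of the aperture in degrees,
#'   in (10, 180).
#' @param depth Radius of the cavity shell around the site C-beta in
#'   Angstrom; the tether region (within ~4 A of CB) stays free.
#' @return A `protein_structure`.
#' @export
make_cone_pocket <- function(aperture_deg = 90, depth = 8.5) {
  stopifnot(aperture_deg > 10, aperture_deg < 180, depth > 5)
  pep <- .orient_on_site(.build_extended_peptide(c("GLY", "ALA", "GLY")))
  cb <- as.numeric(pep[pep$resno == 2L & pep$name == "CB", c("x", "y", "z")])
  half <- .deg2rad(aperture_deg / 2)
  n <- ceiling(4 * pi * depth^2 / 1.0)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  keep <- pts[, 1L] < cos(half)  # cut the aperture cap about +x
  shell <- sweep(depth * pts[keep, , drop = FALSE], 2L, cb, FUN = "+")
  .new_structure(rbind(pep, .dummy_atoms(shell)),
                 source_id = sprintf("cone%.0f", aperture_deg))
}

#' Flat wall fixture
#'
#' The tripeptide oriented with its site axis along +x and a plane of
#' carbon pseudo-atoms at `x = offset`, spaced 1.5 Angstrom.  Accepted
#' conformers can never penetrate the wall: the minimum label-wall
#' distance stays at or above the vdW cutoff.
#'
#' @param offset Wall plane position along x, Angstrom (site CA at the
#'   origin).
#' @param halfwidth Half-extent of the wall in y and z, Angstrom.
#' @return A `protein_structure`.
#' @export
make_wall <- function(offset = 10, halfwidth = 12) {
  stopifnot(offset > 0, halfwidth > 0)
  pep <- .orient_on_site(.build_extended_peptide(c("GLY", "ALA", "GLY")))
  g <- seq(-halfwidth, halfwidth, by = 1.5)
  grid <- expand.grid(y = g, z = g)
  wall <- .dummy_atoms(cbind(offset, grid$y, grid$z))
  .new_structure(rbind(pep, wall), source_id = "wall")
}

#' Spherical cage fixture
#'
#' A closed shell of carbon pseudo-atoms (Fibonacci sphere, ~1 Angstrom
#' spacing) centred on the site's C-beta.  With the default cutoff a
#' small cage leaves no acceptable conformer: everything clashes.
#'
#' @param radius Cage radius in Angstrom.
#' @return A `protein_structure`.
#' @export
make_cage <- function(radius = 2.5) {
  stopifnot(radius > 0)
  pep <- .orient_on_site(.build_extended_peptide(c("GLY", "ALA", "GLY")))
  cb <- as.numeric(pep[pep$resno == 2L & pep$name == "CB", c("x", "y", "z")])
  n <- max(40L, ceiling(4 * pi * radius^2 / 1.0))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  shell <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                          cos(phi))
  shell <- sweep(shell, 2L, cb, FUN = "+")
  .new_structure(rbind(pep, .dummy_atoms(shell)), source_id = "cage")
}

#' Exactly symmetric dimer fixture
#'
#' Two copies of the tripeptide related by an exact rotation about the z
#' axis: chain A displaced from the axis, chain B its rotated image.  The
#' backbone superposition of the two sites has rmsd 0, making the fixture
#' the reference case for "copy and move".
#'
#' @param rotation_deg Rotation relating the protomers (default 180).
#' @param offset Displacement of the protomer CA from the z axis,
#'   Angstrom.
#' @return A `protein_structure` with chains A and B (sites at residue 2).
#' @export
make_symmetric_dimer <- function(rotation_deg = 180, offset = 15) {
  stopifnot(offset > 0)
  a <- .orient_on_site(.build_extended_peptide(c("GLY", "ALA", "GLY")))
  a[, "x"] <- a[, "x"] + offset
  b <- a
  R <- .rotation_about_axis(c(0, 0, 1), rotation_deg)
  xyz <- as.matrix(b[, c("x", "y", "z")]) %*% t(R)
  b[, c("x", "y", "z")] <- xyz
  b$chain <- "B"
  .new_structure(rbind(a, b),
                 source_id = sprintf("dimer%.0f", rotation_deg))
}
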