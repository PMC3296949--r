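# mtssl_model: geometry of the MTSSL (R1) side chain and its kinematics.
#
# The template is built once from ideal internal coordinates (standard
# bond lengths and angles) rather than copied from any crystal structure.
# Atom naming follows the common R1A scheme:
#
#   backbone  N, CA, C, O, CB
#   tether    SG - SD - CE            (disulfide + exocyclic methylene)
#   ring      C3=C4, C5, C2, N1-O1   (2,5-dihydro-pyrrole N-oxyl)
#   methyls   C6, C7 (on C2), C8, C9 (on C5)
#
# Five rotatable torsions connect the backbone to the nitroxide:
#   chi1 N-CA-CB-SG, chi2 CA-CB-SG-SD, chi3 CB-SG-SD-CE,
#   chi4 SG-SD-CE-C3, chi5 SD-CE-C3-C4.
# The ring (with N1, O1 and the four methyls) is one rigid unit.

.MTSSL_BONDS <- list(
  c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"),
  c("CB", "SG"), c("SG", "SD"), c("SD", "CE"), c("CE", "C3"),
  c("C3", "C4"), c("C3", "C2"), c("C4", "C5"), c("C2", "N1"),
  c("C5", "N1"), c("N1", "O1"),
  c("C2", "C6"), c("C2", "C7"), c("C5", "C8"), c("C5", "C9"))

.MTSSL_TORSIONS <- list(
  list(name = "chi1", quad = c("N", "CA", "CB", "SG")),
  list(name = "chi2", quad = c("CA", "CB", "SG", "SD")),
  list(name = "chi3", quad = c("CB", "SG", "SD", "CE")),
  list(name = "chi4", quad = c("SG", "SD", "CE", "C3")),
  list(name = "chi5", quad = c("SD", "CE", "C3", "C4")))

## Bond-graph shortest-path distances between all template atoms (BFS).
.bond_graph_distances <- function(atom_names, bonds) {
  n <- length(atom_names)
  adj <- stats::setNames(vector("list", n), atom_names)
  for (b in bonds) {
    adj[[b[1L]]] <- c(adj[[b[1L]]], b[2L])
    adj[[b[2L]]] <- c(adj[[b[2L]]], b[1L])
  }
  D <- matrix(Inf, n, n, dimnames = list(atom_names, atom_names))
  for (src in atom_names) {
    dist <- stats::setNames(rep(Inf, n), atom_names)
    dist[src] <- 0
    queue <- src
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (dist[v] > dist[u] + 1) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    D[src, ] <- dist
  }
  D
}

## Atoms downstream of the rotating bond of each torsion (moved when the
## dihedral changes), derived from the bond graph with the b-c bond cut.
.rotating_set <- function(atom_names, bonds, bond_b, bond_c) {
  cut <- Filter(function(b) !setequal(b, c(bond_b, bond_c)), bonds)
  D <- .bond_graph_distances(atom_names, cut)
  atom_names[is.finite(D[bond_c, ]) & atom_names != bond_c]
}

## Two tetrahedral substituent directions at a centre whose other two
## bonds point along unit vectors u1, u2; `normal` fixes the out-of-plane
## axis.  Returns a 2 x 3 matrix of unit directions.
.tetra_pair <- function(u1, u2, normal) {
  b <- -.unit(u1 + u2)
  nrm <- .unit(normal - sum(normal * b) * b)
  half <- .deg2rad(109.5 / 2)
  rbind(cos(half) * b + sin(half) * nrm,
        cos(half) * b - sin(half) * nrm)
}

.build_mtssl_coords <- function() {
  xyz <- matrix(NA_real_, nrow = 18L, ncol = 3L,
                dimnames = list(c("N", "CA", "C", "O", "CB", "SG", "SD",
                                  "CE", "C3", "C4", "C5", "C2", "N1", "O1",
                                  "C6", "C7", "C8", "C9"), NULL))
  xyz["N", ] <- c(0, 0, 0)
  xyz["CA", ] <- c(1.458, 0, 0)
  ang <- .deg2rad(180 - 111)
  xyz["C", ] <- xyz["CA", ] + 1.525 * c(cos(ang), sin(ang), 0)
  xyz["O", ] <- .place_atom(xyz["N", ], xyz["CA", ], xyz["C", ],
                            1.231, 120.5, 0)
  xyz["CB", ] <- .place_atom(xyz["C", ], xyz["N", ], xyz["CA", ],
                             1.530, 110.5, -122.5)
  xyz["SG", ] <- .place_atom(xyz["N", ], xyz["CA", ], xyz["CB", ],
                             1.810, 113.8, 180)
  xyz["SD", ] <- .place_atom(xyz["CA", ], xyz["CB", ], xyz["SG", ],
                             2.030, 103.8, 180)
  xyz["CE", ] <- .place_atom(xyz["CB", ], xyz["SG", ], xyz["SD", ],
                             1.810, 103.8, 180)
  xyz["C3", ] <- .place_atom(xyz["SG", ], xyz["SD", ], xyz["CE", ],
                             1.500, 113.4, 180)
  xyz["C4", ] <- .place_atom(xyz["SD", ], xyz["CE", ], xyz["C3", ],
                             1.331, 123.5, 180)

  # Planar 2,5-dihydro-pyrrole N-oxyl ring built in a local frame and
  # grafted onto the placed CE-C3=C4 fragment by exact 3-point
  # superposition (the local CE/C3/C4 triangle is congruent by
  # construction to the global one).
  th3 <- .deg2rad(112)
  C3L <- c(0, 0, 0)
  C4L <- c(1.331, 0, 0)
  C2L <- C3L + 1.512 * c(cos(th3), sin(th3), 0)
  C5L <- c(C4L[1L] - 1.512 * cos(th3), 1.512 * sin(th3), 0)
  axis_x <- 1.331 / 2
  dy <- sqrt(1.472^2 - (axis_x - C2L[1L])^2)
  N1L <- c(axis_x, C2L[2L] + dy, 0)
  O1L <- N1L + c(0, 1.276, 0)
  ceang <- .deg2rad(-123.5)
  CEL <- C3L + 1.500 * c(cos(ceang), sin(ceang), 0)
  m2 <- .tetra_pair(.unit(C3L - C2L), .unit(N1L - C2L), c(0, 0, 1))
  C6L <- C2L + 1.530 * m2[1L, ]
  C7L <- C2L + 1.530 * m2[2L, ]
  m5 <- .tetra_pair(.unit(C4L - C5L), .unit(N1L - C5L), c(0, 0, 1))
  C8L <- C5L + 1.530 * m5[1L, ]
  C9L <- C5L + 1.530 * m5[2L, ]
  local <- rbind(CE = CEL, C3 = C3L, C4 = C4L)
  global <- xyz[c("CE", "C3", "C4"), ]
  tr <- .kabsch(global, local)
  ring <- rbind(C5 = C5L, C2 = C2L, N1 = N1L, O1 = O1L,
                C6 = C6L, C7 = C7L, C8 = C8L, C9 = C9L)
  ring_g <- sweep(ring %*% t(tr$rotation), 2L, tr$translation, FUN = "+")
  xyz[rownames(ring_g), ] <- ring_g
  xyz
}

#' The built-in MTSSL (R1 side chain) label template
#'
#' Atoms, bonds, the five rotatable chi torsions, anchor atoms used for
#' attachment (N, CA, CB) and the spin-center atom (the nitroxide nitrogen
#' N1).  Reference coordinates come from ideal internal geometry; the
#' nitroxide ring with its methyls is treated as a rigid unit.
#'
#' @return An object of class `label_template` with elements `coords`
#'   (18 x 3 matrix, rownames are atom names), `bonds`, `torsions` (each
#'   with `name`, `quad`, `rotating`), `anchor_names`, `spin_center_name`,
#'   `side_chain_names`, `graph_dist` (bond-graph distances) and
#'   `residue_name` (`"R1A"`).
#' @export
mtssl_template <- function() {
  coords <- .build_mtssl_coords()
  atom_names <- rownames(coords)
  torsions <- lapply(.MTSSL_TORSIONS, function(t) {
    t$rotating <- .rotating_set(atom_names, .MTSSL_BONDS,
                                t$quad[2L], t$quad[3L])
    t
  })
  elements <- substr(atom_names, 1L, 1L)
  structure(list(coords = coords,
                 atom_names = atom_names,
                 elements = elements,
                 bonds = .MTSSL_BONDS,
                 torsions = torsions,
                 anchor_names = c("N", "CA", "CB"),
                 spin_center_name = "N1",
                 side_chain_names = setdiff(atom_names,
                                            c("N", "CA", "C", "O", "CB")),
                 graph_dist = .bond_graph_distances(atom_names, .MTSSL_BONDS),
                 residue_name = "R1A"),
            class = "label_template")
}

#' @export
print.label_template <- function(x, ...) {
  cat(sprintf("label template %s: %d atoms, %d bonds, %d torsions, spin center %s\n",
              x$residue_name, nrow(x$coords), length(x$bonds),
              length(x$torsions), x$spin_center_name))
  invisible(x)
}

## Backbone anchor coordinates (N, CA, CB) of a residue; glycine gets an
## ideal C-beta constructed from N, CA, C.
.residue_anchor_coords <- function(res, st) {
  need <- function(nm) {
    row <- res[res$name == nm, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  n <- need("N"); ca <- need("CA"); cb <- need("CB")
  if (is.null(n) || is.null(ca)) {
    stop(sprintf("cannot anchor label at %s:%d%s: missing backbone N/CA",
                 st$chain_id, st$residue_number, st$insertion_code))
  }
  if (is.null(cb)) {
    cc <- need("C")
    if (is.null(cc)) {
      stop(sprintf("cannot anchor label at %s:%d%s: no CB and no C to construct one",
                   st$chain_id, st$residue_number, st$insertion_code))
    }
    cb <- .ideal_cb(n, ca, cc)
  }
  rbind(N = n, CA = ca, CB = cb)
}

#' Attach the label template to a residue
#'
#' Least-squares rigid superposition of the template anchor atoms
#' (N, CA, CB) onto the residue's backbone; glycine sites get an ideal
#' tetrahedral C-beta constructed from N, CA, C.  The residue's own side
#' chain plays no further role (mutation to R1 is implied).
#'
#' @param t A `label_template` from [mtssl_template()].
#' @param s A `protein_structure`.
#' @param st The labeling site (`site_ref`).
#' @return An `attached_label` with the rigidly transformed template
#'   coordinates (`coords`), the `anchor_rmsd` in Angstrom and a recorded
#'   `warning` if the anchor fit is poor (> 0.5 A).
#' @export
attach_label <- function(t, s, st) {
  stopifnot(inherits(t, "label_template"))
  res <- select_residue(s, st)
  target <- .residue_anchor_coords(res, st)
  tr <- .kabsch(target, t$coords[t$anchor_names, ])
  coords <- sweep(t$coords %*% t(tr$rotation), 2L, tr$translation, FUN = "+")
  warn <- NULL
  if (tr$fit_rmsd > 0.5) {
    warn <- sprintf("anchor rmsd %.2f A at %s:%d%s: backbone geometry deviates from ideal",
                    tr$fit_rmsd, st$chain_id, st$residue_number, st$insertion_code)
    warning(warn)
  }
  structure(list(site = st, coords = coords, anchor_rmsd = tr$fit_rmsd,
                 template = t, warning = warn),
            class = "attached_label")
}

#' @export
print.attached_label <- function(x, ...) {
  cat(sprintf("attached %s label at %s:%d%s (anchor rmsd %.3f A)\n",
              x$template$residue_name, x$site$chain_id,
              x$site$residue_number, x$site$insertion_code, x$anchor_rmsd))
  invisible(x)
}

## Core torsion kinematics on a named coordinate matrix: set the five chi
## dihedrals in order chi1 -> chi5 by rigid rotation of each rotating set
## about its b-c bond axis.  Internal geometry is preserved exactly.
.set_torsions <- function(coords, torsions, chi) {
  for (k in seq_along(torsions)) {
    t <- torsions[[k]]
    q <- t$quad
    cur <- .dihedral(coords[q[1L], ], coords[q[2L], ],
                     coords[q[3L], ], coords[q[4L], ])
    delta <- chi[k] - cur
    axis <- coords[q[3L], ] - coords[q[2L], ]
    coords[t$rotating, ] <- .rotate_coords(coords[t$rotating, , drop = FALSE],
                                           coords[q[2L], ], axis, delta)
  }
  coords
}

#' Build a label conformer at given chi angles
#'
#' Rotates the rotating set of each torsion about its bond axis so that
#' the five dihedrals take the requested values (applied chi1 through
#' chi5).  Bond lengths and angles of the template are preserved exactly;
#' only the five set dihedrals change.
#'
#' @param a An `attached_label` (or a `label_template`, to pose the free
#'   label in its reference frame).
#' @param chi Numeric length-5 vector of chi angles in degrees; values are
#'   reduced mod 360.
#' @return A `label_conformer` with `chi`, `coords` and unset clash and
#'   contact fields.
#' @export
apply_torsions <- function(a, chi) {
  stopifnot(length(chi) == 5L, all(is.finite(chi)))
  chi <- .wrap360(as.numeric(chi))
  if (inherits(a, "label_template")) {
    tpl <- a
    coords <- a$coords
    st <- NULL
  } else {
    stopifnot(inherits(a, "attached_label"))
    tpl <- a$template
    coords <- a$coords
    st <- a$site
  }
  coords <- .set_torsions(coords, tpl$torsions, chi)
  structure(list(chi = chi, coords = coords, site = st, template = tpl,
                 clash_count = NA_integer_, contact_count = NA_integer_,
                 snuggly = NA),
            class = "label_conformer")
}

#' @export
print.label_conformer <- function(x, ...) {
  cat(sprintf("label conformer: chi = (%s) deg, clashes = %s, contacts = %s, snuggly = %s\n",
              paste(sprintf("%.1f", x$chi), collapse = ", "),
              x$clash_count, x$contact_count, x$snuggly))
  invisible(x)
}

#' Measure the five chi torsions of a conformer
#'
#' @param c A `label_conformer`, `attached_label` or `label_template`, or
#'   a named coordinate matrix containing the quadruple atoms.
#' @param template Template defining the torsion quadruples (defaults to
#'   the object's own template).
#' @return Numeric length-5 vector of dihedrals in `[0, 360)`, named
#'   chi1..chi5.
#' @export
measure_torsions <- function(c, template = NULL) {
  if (is.matrix(c)) {
    coords <- c
    tpl <- if (is.null(template)) mtssl_template() else template
  } else {
    coords <- c$coords
    tpl <- if (!is.null(template)) template
    else if (!is.null(c$template)) c$template
    else c
  }
  out <- vapply(tpl$torsions, function(t) {
    q <- t$quad
    .dihedral360(coords[q[1L], ], coords[q[2L], ],
                 coords[q[3L], ], coords[q[4L], ])
  }, numeric(1L))
  stats::setNames(out, vapply(tpl$torsions, `[[`, "", "name"))
}

## ---- template text serialization ---------------------------------------

#' Write a label template to a plain-text file
#'
#' Simple line-oriented format (`atom name element x y z`, `bond a b`,
#' `torsion name a b c d`, plus `anchor`/`spin_center` lines) so that
#' alternative labels can be defined and read back with
#' [read_label_template()].
#'
#' @param t A `label_template`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_template <- function(t, path) {
  lines <- c(sprintf("residue %s", t$residue_name),
             sprintf("atom %s %s %.6f %.6f %.6f", t$atom_names, t$elements,
                     t$coords[, 1L], t$coords[, 2L], t$coords[, 3L]),
             vapply(t$bonds, function(b) sprintf("bond %s %s", b[1L], b[2L]),
                    character(1L)),
             vapply(t$torsions, function(x)
               sprintf("torsion %s %s", x$name, paste(x$quad, collapse = " ")),
               character(1L)),
             sprintf("anchor %s", paste(t$anchor_names, collapse = " ")),
             sprintf("spin_center %s", t$spin_center_name))
  writeLines(lines, path)
  invisible(path)
}

#' Read a label template from its plain-text format
#'
#' @param path File written by [write_label_template()].
#' @return A `label_template`.
#' @export
read_label_template <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tok <- strsplit(trimws(lines[nzchar(trimws(lines))]), "[[:space:]]+")
  kind <- vapply(tok, `[[`, "", 1L)
  at <- tok[kind == "atom"]
  nm <- vapply(at, `[[`, "", 2L)
  coords <- t(vapply(at, function(x) as.numeric(x[4:6]), numeric(3L)))
  rownames(coords) <- nm
  bonds <- lapply(tok[kind == "bond"], function(x) x[2:3])
  quads <- lapply(tok[kind == "torsion"], function(x)
    list(name = x[2L], quad = x[3:6]))
  torsions <- lapply(quads, function(t) {
    t$rotating <- .rotating_set(nm, bonds, t$quad[2L], t$quad[3L])
    t
  })
  anchors <- tok[kind == "anchor"][[1L]][-1L]
  spin <- tok[kind == "spin_center"][[1L]][2L]
  resname <- tok[kind == "residue"][[1L]][2L]
  structure(list(coords = coords, atom_names = nm,
                 elements = vapply(at, `[[`, "", 3L),
                 bonds = bonds, torsions = torsions,
                 anchor_names = anchors, spin_center_name = spin,
                 side_chain_names = setdiff(nm, c("N", "CA", "C", "O", "CB")),
                 graph_dist = .bond_graph_distances(nm, bonds),
                 residue_name = resname),
            class = "label_template")
}
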