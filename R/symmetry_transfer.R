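# symmetry_transfer: "copy and move" a computed ensemble onto a
# symmetry-related site of a multimer by least-squares backbone
# superposition, instead of searching again.

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rigid transform (rotation + translation, no reflection)
#' mapping `mov_points` onto `ref_points`.
#'
#' @param ref_points,mov_points Matching n x 3 coordinate matrices,
#'   n >= 3, not colinear.
#' @return A `rigid_transform` with `rotation` (3 x 3, det +1),
#'   `translation` and `fit_rmsd` (Angstrom).
#' @export
superpose <- function(ref_points, mov_points) {
  tr <- .kabsch(ref_points, mov_points)
  structure(tr, class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: fit rmsd %.4f A, translation (%.2f, %.2f, %.2f)\n",
              x$fit_rmsd, x$translation[1L], x$translation[2L],
              x$translation[3L]))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform`.
#' @param coords n x 3 matrix (or length-3 vector).
#' @return Transformed coordinates of the same shape.
#' @export
apply_transform <- function(tr, coords) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (is.null(dim(coords))) {
    return(as.numeric(tr$rotation %*% coords + tr$translation))
  }
  out <- sweep(coords %*% t(tr$rotation), 2L, tr$translation, FUN = "+")
  dimnames(out) <- dimnames(coords)
  out
}

## Single-residue superposition frame: backbone N, CA, C, O and CB
## (constructed for glycine).  O is used when present.
.residue_frame <- function(s, st) {
  res <- select_residue(s, st)
  anchors <- .residue_anchor_coords(res, st)  # N, CA, CB
  extra <- lapply(c("C", "O"), function(nm) {
    row <- res[res$name == nm, , drop = FALSE]
    if (nrow(row) == 0L) NULL else as.numeric(row[1L, c("x", "y", "z")])
  })
  names(extra) <- c("C", "O")
  if (is.null(extra$C)) {
    stop(sprintf("missing backbone C at %s:%d%s", st$chain_id,
                 st$residue_number, st$insertion_code))
  }
  out <- rbind(anchors, C = extra$C)
  if (!is.null(extra$O)) out <- rbind(out, O = extra$O)
  out
}

#' Transfer an ensemble to a symmetry-related site ("copy and move")
#'
#' Superposes the backbone frame (N, CA, C, O, CB) of the source residue
#' onto that of the target residue and maps every conformer by the
#' resulting rigid transform.  The transfer is an isometry: all intra- and
#' inter-conformer distances are preserved.  With `revalidate = TRUE` the
#' clash test is re-run against the target-site environment and violating
#' conformers are dropped (with a logged count) -- recommended for
#' pseudo-symmetric assemblies.
#'
#' @param e The computed `label_ensemble` at the source site.
#' @param s The `protein_structure` containing both sites.
#' @param target The target `site_ref`.
#' @param revalidate Re-check clashes at the target site (default
#'   `FALSE`, faithful "copy" semantics).
#' @return A `label_ensemble` at the target site; the applied transform is
#'   attached as element `transform`.
#' @export
copy_move <- function(e, s, target, revalidate = FALSE) {
  stopifnot(inherits(e, "label_ensemble"), inherits(target, "site_ref"))
  src_frame <- .residue_frame(s, e$site)
  tgt_frame <- .residue_frame(s, target)
  common <- intersect(rownames(src_frame), rownames(tgt_frame))
  tr <- superpose(tgt_frame[common, , drop = FALSE],
                  src_frame[common, , drop = FALSE])
  if (tr$fit_rmsd > 0.5) {
    warning(sprintf("backbone fit rmsd %.2f A: source and target sites may not be symmetry-equivalent", tr$fit_rmsd))
  }
  moved <- e
  moved$site <- target
  moved$transform <- tr
  moved$conformers <- lapply(e$conformers, function(cf) {
    cf$coords <- apply_transform(tr, cf$coords)
    cf$site <- target
    cf
  })
  if (!is.null(moved$attached)) {
    moved$attached$coords <- apply_transform(tr, moved$attached$coords)
    moved$attached$site <- target
  }
  if (revalidate && length(moved$conformers) > 0L) {
    env <- environment_for_site(s, target)
    env_xyz <- .env_coords(env)
    counts <- vapply(moved$conformers, function(cf) {
      .count_clashes(cf$coords[cf$template$side_chain_names, , drop = FALSE],
                     env_xyz, e$params$vdw_cutoff)
    }, integer(1L))
    keep <- counts <= e$params$allowed_clashes
    if (any(!keep)) {
      message(sprintf("copy_move: dropped %d of %d conformers clashing at the target site",
                      sum(!keep), length(keep)))
    }
    moved$conformers <- Map(function(cf, n_cl) {
      cf$clash_count <- n_cl
      cf
    }, moved$conformers[keep], counts[keep])
    moved$dropped <- sum(!keep)
  }
  moved
}
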