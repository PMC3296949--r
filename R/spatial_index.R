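# Spatial hash grid for fast fixed-radius neighbour queries over atom
# coordinates.  Cells are cubes of side `cell_size`; atoms are bucketed by
# the integer cell containing them and a query inspects only the cells
# overlapping the query ball.  Results are exact: candidates are filtered
# by true Euclidean distance, and the ball is closed (d <= r).

#' Build a spatial index over a set of atoms
#'
#' @param atoms Atom data.frame (columns `x`, `y`, `z`, as produced by
#'   [read_pdb()] or [environment_for_site()]), or a numeric n x 3 matrix.
#' @param cell_size Cell edge length in Angstrom (> 0).  A value close to
#'   the typical query radius is a good choice.
#' @return An object of class `spatial_index`.
#' @export
build_spatial_index <- function(atoms, cell_size = 4) {
  stopifnot(cell_size > 0)
  if (is.matrix(atoms)) {
    coords <- atoms
    meta <- NULL
  } else {
    coords <- as.matrix(atoms[, c("x", "y", "z")])
    meta <- atoms
  }
  storage.mode(coords) <- "double"
  cells <- new.env(hash = TRUE, parent = emptyenv())
  n <- nrow(coords)
  if (n > 0L) {
    ijk <- floor(coords / cell_size)
    key <- paste(ijk[, 1L], ijk[, 2L], ijk[, 3L], sep = ",")
    idx_by_cell <- split(seq_len(n), key)
    for (k in names(idx_by_cell)) assign(k, idx_by_cell[[k]], envir = cells)
  }
  structure(list(cell_size = cell_size, cells = cells,
                 coords = coords, atoms = meta, n = n),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("spatial index: %d atoms, cell size %.2f A, %d occupied cells\n",
              x$n, x$cell_size, length(ls(x$cells))))
  invisible(x)
}

## Indices of atoms with Euclidean distance <= r from point (closed ball).
.query_radius_idx <- function(idx, point, r) {
  stopifnot(inherits(idx, "spatial_index"), r > 0)
  if (idx$n == 0L) return(integer(0L))
  cs <- idx$cell_size
  lo <- floor((point - r) / cs)
  hi <- floor((point + r) / cs)
  cand <- integer(0L)
  for (i in lo[1L]:hi[1L]) {
    for (j in lo[2L]:hi[2L]) {
      for (k in lo[3L]:hi[3L]) {
        key <- paste(i, j, k, sep = ",")
        hit <- get0(key, envir = idx$cells, inherits = FALSE)
        if (!is.null(hit)) cand <- c(cand, hit)
      }
    }
  }
  if (length(cand) == 0L) return(integer(0L))
  d2 <- (idx$coords[cand, 1L] - point[1L])^2 +
    (idx$coords[cand, 2L] - point[2L])^2 +
    (idx$coords[cand, 3L] - point[3L])^2
  sort(cand[d2 <= r * r])
}

#' Radius query against a spatial index
#'
#' Returns exactly the indexed atoms with Euclidean distance `<= r` from
#' `point` (closed ball; an atom exactly at the radius is included).
#'
#' @param idx A `spatial_index`.
#' @param point Numeric length-3 query point (Angstrom).
#' @param r Query radius in Angstrom (> 0).
#' @return The matching atom rows (data.frame) if the index was built from
#'   an atom table, else the matching coordinate rows; the matched indices
#'   are attached as attribute `"indices"`.
#' @export
query_radius <- function(idx, point, r) {
  hits <- .query_radius_idx(idx, as.numeric(point), r)
  out <- if (!is.null(idx$atoms)) idx$atoms[hits, , drop = FALSE]
  else idx$coords[hits, , drop = FALSE]
  attr(out, "indices") <- hits
  out
}
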