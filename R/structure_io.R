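# structure_io: read protein structures from PDB format, select residues
# and clash environments, and write structures/ensembles back out.
#
# A structure is held as a plain data.frame of atoms (one row per atom)
# wrapped in a "protein_structure" S3 object.  Parsing of PDB files is
# delegated to bio3d::read.pdb; a pre-scan of the raw lines provides
# line-numbered errors for malformed coordinate fields, which bio3d does
# not report.

#' Reference a labeling site by chain and residue number
#'
#' @param chain_id Chain identifier (single character, e.g. `"A"`).
#' @param residue_number Author residue number (integer).
#' @param insertion_code Insertion code, `""` if none.
#' @return An object of class `site_ref`.
#' @examples
#' site("A", 131)
#' @export
site <- function(chain_id, residue_number, insertion_code = "") {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  residue_number <- as.integer(residue_number)
  stopifnot(length(residue_number) == 1L, !is.na(residue_number))
  structure(list(chain_id = chain_id,
                 residue_number = residue_number,
                 insertion_code = insertion_code),
            class = "site_ref")
}

#' @export
print.site_ref <- function(x, ...) {
  cat(sprintf("site %s:%d%s\n", x$chain_id, x$residue_number,
              x$insertion_code))
  invisible(x)
}

#' Parse a "CHAIN:RESNO" site string
#'
#' @param text Site given as `"A:131"` (optionally `"A:131B"` with an
#'   insertion code suffix).
#' @return A `site_ref`.
#' @export
parse_site <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z0-9]):(-?[0-9]+)([A-Za-z]?)$", text))[[1L]]
  if (length(m) == 0L) stop("cannot parse site '", text, "'; expected CHAIN:RESNO")
  site(m[2L], as.integer(m[3L]), m[4L])
}

.new_structure <- function(atoms, model_number = 1L, source_id = "") {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 model_number = as.integer(model_number),
                 source_id = source_id),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("protein structure '%s': %d atoms, %d residues, chains %s (model %d)\n",
              x$source_id, nrow(a),
              length(unique(paste(a$chain, a$resno, a$ins))),
              paste(sort(unique(a$chain)), collapse = ","),
              x$model_number))
  invisible(x)
}

## Element symbol guessed from a PDB atom name when the element column is
## absent or blank.  Two-letter elements relevant here: only a handful.
.guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA", "CU", "NI", "SE")
  # PDB convention: names like "CA " are carbon-alpha, not calcium, when they
  # come from an ATOM record; treat leading character as the element.
  ifelse(nchar(nm) == 0L, "X", substr(nm, 1L, 1L))
}

## Pre-scan raw PDB lines for malformed coordinate fields; returns invisibly
## or stops with the offending line number.
.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      fld <- substr(ln, cols[1L], cols[2L])
      if (is.na(suppressWarnings(as.numeric(fld)))) {
        stop(sprintf("malformed coordinate field in PDB input at line %d: '%s'",
                     i, trimws(fld)))
      }
    }
  }
  invisible(idx)
}

#' Read a protein structure from PDB format
#'
#' Reads PDB text or a PDB file into a `protein_structure`.  Only the
#' requested MODEL of a multi-MODEL (e.g. NMR) file is returned; alternate
#' locations are resolved to the highest-occupancy altloc (ties favour
#' altloc `"A"`).  ANISOU and CONECT records are ignored.
#'
#' @param source Path to a PDB file, or a character string/vector of PDB
#'   text (recognised by embedded newlines or ATOM records).
#' @param model Which MODEL to return (default 1, the first).
#' @return A `protein_structure` whose `atoms` data.frame has columns
#'   `name`, `element`, `x`, `y`, `z`, `resno`, `ins`, `chain`, `resid`,
#'   `het` (logical) and `hyd` (logical, hydrogen/deuterium).
#' @export
read_pdb <- function(source, model = 1L) {
  is_text <- length(source) > 1L || grepl("\n", source[1L]) ||
    grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", source[1L])
  if (is_text) {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n"))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    src_id <- "pdb-text"
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    lines <- readLines(source, warn = FALSE)
    path <- source
    src_id <- sub("\\.(pdb|ent)$", "", basename(source))
  }
  .validate_pdb_lines(lines)
  if (!any(substr(lines, 1L, 6L) %in% c("ATOM  ", "HETATM"))) {
    stop("empty structure: no ATOM/HETATM records in PDB input")
  }
  n_models <- max(1L, sum(substr(lines, 1L, 5L) == "MODEL"))
  if (model > n_models) {
    stop(sprintf("model %d requested but input has %d model(s)", model, n_models))
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = n_models > 1L, rm.alt = FALSE,
                    verbose = FALSE)
  )
  at <- pdb$atom
  if (n_models > 1L) {
    xyz <- pdb$xyz[model, ]
    at$x <- xyz[seq(1L, length(xyz), by = 3L)]
    at$y <- xyz[seq(2L, length(xyz), by = 3L)]
    at$z <- xyz[seq(3L, length(xyz), by = 3L)]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", nrow(at))
  elem <- toupper(trimws(ifelse(is.na(elem) | elem == "",
                                .guess_element(at$elety), elem)))
  ins <- ifelse(is.na(at$insert), "", at$insert)
  chain <- ifelse(is.na(at$chain), "", at$chain)
  atoms <- data.frame(name = at$elety,
                      element = elem,
                      x = at$x, y = at$y, z = at$z,
                      resno = at$resno,
                      ins = ins,
                      chain = chain,
                      resid = at$resid,
                      het = at$type == "HETATM",
                      hyd = elem %in% c("H", "D"),
                      alt = ifelse(is.na(at$alt), "", at$alt),
                      occ = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  atoms <- .resolve_altlocs(atoms)
  atoms$alt <- NULL
  atoms$occ <- NULL
  .new_structure(atoms, model_number = model, source_id = src_id)
}

## Keep one altloc per (chain, resno, ins, name): highest occupancy, ties
## broken in favour of altloc "A" (then alphabetically).
.resolve_altlocs <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    if (length(ii) == 1L) return(ii)
    sub <- atoms[ii, ]
    ord <- order(-sub$occ, sub$alt != "A", sub$alt)
    ii[ord[1L]]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

.site_rows <- function(s, st) {
  a <- s$atoms
  which(a$chain == st$chain_id &
          a$resno == st$residue_number &
          a$ins == st$insertion_code)
}

#' Select all atoms of one residue
#'
#' @param s A `protein_structure`.
#' @param st A `site_ref`.
#' @return The atom data.frame rows of that residue.
#' @export
select_residue <- function(s, st) {
  stopifnot(inherits(s, "protein_structure"), inherits(st, "site_ref"))
  rows <- .site_rows(s, st)
  if (length(rows) == 0L) {
    stop(sprintf("site not found: %s:%d%s", st$chain_id, st$residue_number,
                 st$insertion_code))
  }
  res <- s$atoms[rows, , drop = FALSE]
  if (length(unique(res$resid)) > 1L) {
    stop(sprintf("ambiguous site %s:%d%s: matches more than one residue",
                 st$chain_id, st$residue_number, st$insertion_code))
  }
  res
}

#' Clash/contact environment of a labeling site
#'
#' All heavy atoms of the structure except the labeled residue itself.
#' Hydrogens are always excluded (the vdW cutoff is defined in heavy-atom
#' terms); waters and hetero atoms (ligands, ions) are excluded by default.
#'
#' The backbone atoms (N, CA, C, O) of the two sequence-adjacent residues
#' are also excluded by default.  They sit 4-6 covalent bonds from the
#' label tether, so their proximity is dictated by backbone geometry, not
#' by sterics: counting them against a uniform heavy-atom cutoff would
#' reject conformations that spin-labeled crystal structures actually
#' show, and would leave most surface sites unlabelable at default
#' parameters.  Set `exclude_adjacent_backbone = FALSE` for the raw
#' environment.
#'
#' @param s A `protein_structure`.
#' @param st The labeling site (`site_ref`).
#' @param include_hetero Keep non-water HETATM records? Default `FALSE`.
#' @param include_waters Keep waters (HOH/WAT/DOD)? Default `FALSE`.
#' @param exclude_adjacent_backbone Drop N/CA/C/O of residues i-1 and i+1
#'   on the labeled chain? Default `TRUE`.
#' @return Atom data.frame of the environment.
#' @export
environment_for_site <- function(s, st, include_hetero = FALSE,
                                 include_waters = FALSE,
                                 exclude_adjacent_backbone = TRUE) {
  select_residue(s, st)  # validates that the site resolves
  a <- s$atoms
  own <- seq_len(nrow(a)) %in% .site_rows(s, st)
  water <- a$resid %in% c("HOH", "WAT", "DOD")
  adjacent_bb <- exclude_adjacent_backbone &
    a$chain == st$chain_id &
    abs(a$resno - st$residue_number) == 1L &
    a$name %in% c("N", "CA", "C", "O")
  keep <- !own & !a$hyd & !adjacent_bb &
    (include_waters | !water) &
    (include_hetero | !(a$het & !water))
  a[keep, , drop = FALSE]
}

## ---- PDB writing --------------------------------------------------------

## Format one ATOM record (fixed-width PDB v3 layout).
.format_atom_record <- function(serial, name, resid, chain, resno, ins,
                                x, y, z, element, het = FALSE) {
  name4 <- if (nchar(name) >= 4L) substr(name, 1L, 4L) else
    formatC(paste0(" ", name), width = -4L)
  sprintf("%-6s%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial %% 100000L, name4,
          substr(resid, 1L, 3L), substr(chain, 1L, 1L), resno %% 10000L,
          ifelse(ins == "", " ", ins), x, y, z, 1, 0, element)
}

.structure_pdb_lines <- function(s) {
  a <- s$atoms
  vapply(seq_len(nrow(a)), function(i) {
    .format_atom_record(i, a$name[i], a$resid[i], a$chain[i], a$resno[i],
                        a$ins[i], a$x[i], a$y[i], a$z[i], a$element[i],
                        a$het[i])
  }, character(1L))
}

#' Write a structure to a PDB file
#'
#' @param s A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  writeLines(c(.structure_pdb_lines(s), "END"), path)
  invisible(path)
}
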