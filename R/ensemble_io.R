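# ensemble_io: multi-MODEL PDB export of a conformer ensemble (one MODEL
# per conformer, REMARK 300 metadata per model, residue name R1A) and its
# re-import, plus the flat conformer table.

#' Write a label ensemble to a multi-MODEL PDB file
#'
#' One MODEL per conformer with standard ATOM records (residue name from
#' the template, author numbering of the labeled site); chi angles, clash
#' and contact counts and the snuggly flag of each conformer are recorded
#' in a REMARK 300 line inside its MODEL block.
#'
#' @param e A non-empty `label_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(e, path) {
  stopifnot(inherits(e, "label_ensemble"))
  if (length(e$conformers) == 0L) stop("cannot write an empty ensemble")
  st <- e$site
  p <- e$params
  hdr <- c("REMARK 300 SPINLABELR ENSEMBLE",
           sprintf("REMARK 300 SITE %s %d %s", st$chain_id,
                   st$residue_number,
                   if (st$insertion_code == "") "-" else st$insertion_code),
           sprintf("REMARK 300 SOURCE %s", e$source_structure_id),
           sprintf("REMARK 300 PARAMS THOROUGHNESS %s TRIALS %d VDW %.3f CLASHES %d ICLASH %.3f SEED %d",
                   p$thoroughness, p$trials, p$vdw_cutoff, p$allowed_clashes,
                   p$internal_clash_cutoff, p$seed))
  blocks <- lapply(seq_along(e$conformers), function(i) {
    cf <- e$conformers[[i]]
    tpl <- cf$template
    nm <- rownames(cf$coords)
    rec <- vapply(seq_along(nm), function(j) {
      .format_atom_record(j, nm[j], tpl$residue_name, st$chain_id,
                          st$residue_number, st$insertion_code,
                          cf$coords[j, 1L], cf$coords[j, 2L],
                          cf$coords[j, 3L],
                          tpl$elements[j])
    }, character(1L))
    c(sprintf("MODEL %8d", i),
      sprintf("REMARK 300 CONFORMER %d CHI %s CLASHES %s CONTACTS %s SNUGGLY %s",
              i, paste(sprintf("%.4f", cf$chi), collapse = " "),
              cf$clash_count,
              if (is.na(cf$contact_count)) "-" else cf$contact_count,
              if (is.na(cf$snuggly)) "-" else as.integer(cf$snuggly)),
      rec, "ENDMDL")
  })
  writeLines(c(hdr, unlist(blocks), "END"), path)
  invisible(path)
}

#' Read a label ensemble written by [write_ensemble_pdb()]
#'
#' @param path Ensemble PDB file.
#' @param template Label template used to interpret the atoms (default
#'   [mtssl_template()]).
#' @return A `label_ensemble` with coordinates, chi values, clash/contact
#'   counts and snuggly flags restored.
#' @export
read_ensemble_pdb <- function(path, template = mtssl_template()) {
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  site_ln <- grep("^REMARK 300 SITE ", lines, value = TRUE)
  if (length(site_ln) == 0L) stop("not an ensemble PDB: missing REMARK 300 SITE")
  tok <- strsplit(trimws(site_ln[1L]), "[[:space:]]+")[[1L]]
  st <- site(tok[4L], as.integer(tok[5L]),
             if (tok[6L] == "-") "" else tok[6L])
  src <- sub("^REMARK 300 SOURCE ", "",
             grep("^REMARK 300 SOURCE ", lines, value = TRUE)[1L])
  par_ln <- grep("^REMARK 300 PARAMS ", lines, value = TRUE)
  params <- NULL
  if (length(par_ln) > 0L) {
    pt <- strsplit(trimws(par_ln[1L]), "[[:space:]]+")[[1L]]
    val <- function(key) pt[which(pt == key) + 1L]
    params <- search_params(thoroughness = val("THOROUGHNESS"),
                            trials = as.integer(val("TRIALS")),
                            vdw_cutoff = as.numeric(val("VDW")),
                            allowed_clashes = as.integer(val("CLASHES")),
                            internal_clash_cutoff = as.numeric(val("ICLASH")),
                            seed = as.integer(val("SEED")),
                            force = TRUE)
  }
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("malformed ensemble PDB: unbalanced MODEL/ENDMDL records")
  }
  conformers <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    at <- blk[substr(blk, 1L, 6L) %in% c("ATOM  ", "HETATM")]
    nm <- trimws(substr(at, 13L, 16L))
    coords <- cbind(as.numeric(substr(at, 31L, 38L)),
                    as.numeric(substr(at, 39L, 46L)),
                    as.numeric(substr(at, 47L, 54L)))
    rownames(coords) <- nm
    meta <- grep("^REMARK 300 CONFORMER ", blk, value = TRUE)
    chi <- clashes <- contacts <- snug <- NA
    if (length(meta) > 0L) {
      mt <- strsplit(trimws(meta[1L]), "[[:space:]]+")[[1L]]
      chi_i <- which(mt == "CHI")
      chi <- as.numeric(mt[(chi_i + 1L):(chi_i + 5L)])
      clashes <- suppressWarnings(as.integer(mt[which(mt == "CLASHES") + 1L]))
      ct <- mt[which(mt == "CONTACTS") + 1L]
      contacts <- if (ct == "-") NA_integer_ else as.integer(ct)
      sn <- mt[which(mt == "SNUGGLY") + 1L]
      snug <- if (sn == "-") NA else as.logical(as.integer(sn))
    }
    if (anyNA(chi)) {
      chi <- unname(measure_torsions(coords, template = template))
    }
    structure(list(chi = chi, coords = coords, site = st,
                   template = template,
                   clash_count = clashes,
                   contact_count = contacts, snuggly = snug),
              class = "label_conformer")
  })
  structure(list(site = st, conformers = conformers, params = params,
                 trials_run = if (!is.null(params)) params$trials
                 else length(conformers),
                 source_structure_id = src),
            class = "label_ensemble")
}

#' Flat conformer table of an ensemble
#'
#' @param e A `label_ensemble`.
#' @return A data.frame with one row per conformer: `model_id`,
#'   `chi1`..`chi5`, `clash_count`, `contact_count`, `snuggly`.
#' @export
ensemble_table <- function(e) {
  stopifnot(inherits(e, "label_ensemble"))
  if (length(e$conformers) == 0L) {
    return(data.frame(model_id = integer(0L), chi1 = numeric(0L),
                      chi2 = numeric(0L), chi3 = numeric(0L),
                      chi4 = numeric(0L), chi5 = numeric(0L),
                      clash_count = integer(0L),
                      contact_count = integer(0L), snuggly = logical(0L)))
  }
  chis <- .chi_matrix(e)
  data.frame(model_id = seq_along(e$conformers),
             chi1 = chis[, 1L], chi2 = chis[, 2L], chi3 = chis[, 3L],
             chi4 = chis[, 4L], chi5 = chis[, 5L],
             clash_count = vapply(e$conformers, `[[`, integer(1L),
                                  "clash_count"),
             contact_count = vapply(e$conformers, function(cf)
               as.integer(cf$contact_count), integer(1L)),
             snuggly = vapply(e$conformers, function(cf)
               if (is.na(cf$snuggly)) NA else isTRUE(cf$snuggly),
               logical(1L)))
}
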