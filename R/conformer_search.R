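# conformer_search: the core search algorithm.  Chi torsions are drawn
# independently and uniformly on [0, 360); a trial conformer is rejected
# if the label clashes with itself (internal clash) or has more than
# `allowed_clashes` sub-cutoff contacts with the protein environment.
# No rotamer weighting and no energies: every accepted conformer counts
# equally.

.THOROUGHNESS_TRIALS <- c(painstaking = 1500L, thorough = 300L,
                          normal = 90L, quick = 10L)

#' Search parameters for the conformer search
#'
#' @param thoroughness One of `"painstaking"` (1500 trials), `"thorough"`
#'   (300), `"normal"` (90, the default) or `"quick"` (10).
#' @param trials Override the trial count derived from `thoroughness`.
#' @param vdw_cutoff Clash cutoff in Angstrom.  A label atom closer than
#'   this to any environment atom is a clash; the same cutoff is used for
#'   all element pairs.  Default 3.4 (typical carbon-carbon packing
#'   distance); the sanctioned range is 2.6 (a hydrogen-bond length,
#'   heavy-atom to heavy-atom) to 3.4.  Values outside the range require
#'   `force = TRUE` and draw a warning.
#' @param allowed_clashes How many sub-cutoff contacts an accepted
#'   conformer may have, between 0 (default) and 5.  Raise this (or lower
#'   `vdw_cutoff`) for low-resolution structures, flexible regions or
#'   homology models where apparent clashes may not exist in solution.
#' @param internal_clash_cutoff Label self-clash cutoff in Angstrom
#'   (default 2.0); applies to atom pairs more than 3 bonds apart.
#' @param seed RNG seed for the search.  `NULL` (default) draws a seed
#'   from the session RNG and records it, so any search can be replayed.
#' @param force Allow parameters outside their sanctioned ranges
#'   (a caution is issued).
#' @return A `search_params` object.
#' @export
search_params <- function(thoroughness = c("normal", "quick", "thorough",
                                           "painstaking"),
                          trials = NULL, vdw_cutoff = 3.4,
                          allowed_clashes = 0L,
                          internal_clash_cutoff = 2.0,
                          seed = NULL, force = FALSE) {
  thoroughness <- match.arg(thoroughness)
  if (is.null(trials)) trials <- .THOROUGHNESS_TRIALS[[thoroughness]]
  trials <- as.integer(trials)
  stopifnot(trials >= 1L, internal_clash_cutoff > 0)
  if (vdw_cutoff < 2.6 || vdw_cutoff > 3.4) {
    if (!force) {
      stop(sprintf("vdw_cutoff %.2f is outside the sanctioned range [2.6, 3.4] A; use force = TRUE to override", vdw_cutoff))
    }
    warning(sprintf("caution: vdw_cutoff %.2f A is outside the sanctioned range [2.6, 3.4]", vdw_cutoff))
  }
  allowed_clashes <- as.integer(allowed_clashes)
  if (allowed_clashes < 0L || allowed_clashes > 5L) {
    if (!force) {
      stop("allowed_clashes must be between 0 and 5; use force = TRUE to override")
    }
    warning(sprintf("caution: allowed_clashes %d is outside the sanctioned range [0, 5]", allowed_clashes))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(thoroughness = thoroughness, trials = trials,
                 vdw_cutoff = vdw_cutoff, allowed_clashes = allowed_clashes,
                 internal_clash_cutoff = internal_clash_cutoff,
                 seed = as.integer(seed)),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf("search: %s (%d trials), vdW cutoff %.2f A, allowed clashes %d, seed %d\n",
              x$thoroughness, x$trials, x$vdw_cutoff, x$allowed_clashes,
              x$seed))
  invisible(x)
}

## Environment atoms as a coordinate matrix, whatever form they come in.
.env_coords <- function(env) {
  if (inherits(env, "spatial_index")) env$coords
  else if (is.matrix(env)) env
  else as.matrix(env[, c("x", "y", "z")])
}

## Number of distinct environment atoms strictly closer than `cutoff` to
## any of the rows of `label_xyz`.  d == cutoff is NOT a clash.
.count_clashes <- function(label_xyz, env_xyz, cutoff) {
  if (nrow(env_xyz) == 0L || nrow(label_xyz) == 0L) return(0L)
  d2 <- .dist2_matrix(env_xyz, label_xyz)
  mind2 <- do.call(pmin, as.data.frame(d2))
  sum(mind2 < cutoff^2)
}

#' Count clashes of a conformer with the protein environment
#'
#' A clash is an environment atom whose distance to any clash-tested label
#' atom (the side-chain atoms; the anchor/backbone atoms coincide with the
#' residue and are exempt) is strictly below the vdW cutoff.  Each
#' environment atom is counted at most once, and the same cutoff applies
#' to all element pairs.
#'
#' @param c A `label_conformer`.
#' @param env Environment atoms: a `spatial_index`, an atom data.frame or
#'   a coordinate matrix.
#' @param cutoff vdW cutoff in Angstrom (> 0).
#' @return Integer clash count.
#' @export
clash_count <- function(c, env, cutoff = 3.4) {
  stopifnot(inherits(c, "label_conformer"), cutoff > 0)
  label_xyz <- c$coords[c$template$side_chain_names, , drop = FALSE]
  .count_clashes(label_xyz, .env_coords(env), cutoff)
}

## Pair index of label atoms more than 3 bonds apart, precomputed once.
.internal_pairs <- function(template) {
  gd <- template$graph_dist
  which(upper.tri(gd) & gd > 3, arr.ind = TRUE)
}

.has_internal_clash <- function(coords, pairs, cutoff) {
  d2 <- rowSums((coords[pairs[, 1L], , drop = FALSE] -
                   coords[pairs[, 2L], , drop = FALSE])^2)
  any(d2 < cutoff^2)
}

#' Test a conformer for internal (self) clashes
#'
#' `TRUE` iff any pair of label atoms separated by more than 3 bonds in
#' the template bond graph is closer than `cutoff`.  Bonded, 1-3 and 1-4
#' neighbours are exempt, so gauche states are not penalised.
#'
#' @param c A `label_conformer`.
#' @param cutoff Self-clash cutoff in Angstrom (default 2.0).
#' @return Logical.
#' @export
internal_clash <- function(c, cutoff = 2.0) {
  stopifnot(inherits(c, "label_conformer"))
  .has_internal_clash(c$coords, .internal_pairs(c$template), cutoff)
}

## Longest possible reach of any side-chain atom from CB, for environment
## prefiltering: fully extended chain length, rounded up generously.
.LABEL_REACH <- 12

#' Run the stochastic conformer search at a site
#'
#' Attaches the label, then performs `params$trials` generation/check
#' cycles: draw chi1..chi5 independently uniform on `[0, 360)`, build the
#' conformer, discard it on an internal clash or when its environment
#' clash count exceeds `allowed_clashes`, keep it otherwise.  The same
#' seed always reproduces the identical chi sequence and accepted set.
#'
#' When no conformer survives, an empty ensemble is returned together with
#' an advisory message suggesting a larger vdW cutoff, more allowed
#' clashes or a deeper search; the search never relaxes its own
#' parameters.
#'
#' @param s A `protein_structure`.
#' @param st The labeling site (`site_ref`).
#' @param params A [search_params()] object.
#' @param template Label template (default [mtssl_template()]).
#' @param include_hetero,include_waters Environment composition, see
#'   [environment_for_site()].
#' @return A `label_ensemble`: accepted conformers, the parameters that
#'   produced them, `trials_run` and the source structure id.
#' @export
run_search <- function(s, st, params = search_params(),
                       template = mtssl_template(),
                       include_hetero = FALSE, include_waters = FALSE) {
  stopifnot(inherits(params, "search_params"))
  attached <- attach_label(template, s, st)
  env <- environment_for_site(s, st, include_hetero = include_hetero,
                              include_waters = include_waters)
  env_xyz <- .env_coords(env)
  # prefilter environment to atoms the label can possibly reach
  cb <- attached$coords["CB", ]
  reach2 <- (.LABEL_REACH + params$vdw_cutoff)^2
  near <- rowSums(sweep(env_xyz, 2L, cb)^2) <= reach2
  env_near <- env_xyz[near, , drop = FALSE]

  pairs <- .internal_pairs(template)
  side <- template$side_chain_names

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(params$seed)
  chi_mat <- matrix(stats::runif(params$trials * 5L, 0, 360),
                    nrow = params$trials, ncol = 5L, byrow = TRUE)

  conformers <- vector("list", params$trials)
  n_acc <- 0L
  for (t in seq_len(params$trials)) {
    coords <- .set_torsions(attached$coords, template$torsions, chi_mat[t, ])
    if (.has_internal_clash(coords, pairs, params$internal_clash_cutoff)) next
    n_cl <- .count_clashes(coords[side, , drop = FALSE], env_near,
                           params$vdw_cutoff)
    if (n_cl > params$allowed_clashes) next
    n_acc <- n_acc + 1L
    conformers[[n_acc]] <- structure(
      list(chi = .wrap360(chi_mat[t, ]), coords = coords, site = st,
           template = template, clash_count = n_cl,
           contact_count = NA_integer_, snuggly = NA),
      class = "label_conformer")
  }
  conformers <- conformers[seq_len(n_acc)]
  if (n_acc == 0L) {
    message(sprintf(paste0(
      "no conformers found at %s:%d%s with vdW cutoff %.2f and %d allowed ",
      "clashes; consider raising the vdW cutoff, allowing more clashes or ",
      "increasing the thoroughness -- the site may also be too occluded to label"),
      st$chain_id, st$residue_number, st$insertion_code,
      params$vdw_cutoff, params$allowed_clashes))
  }
  structure(list(site = st, conformers = conformers, params = params,
                 trials_run = params$trials,
                 source_structure_id = s$source_id,
                 attached = attached),
            class = "label_ensemble")
}

#' @export
print.label_ensemble <- function(x, ...) {
  n_sn <- sum(vapply(x$conformers, function(cf) isTRUE(cf$snuggly), logical(1L)))
  cat(sprintf("label ensemble at %s:%d%s: %d conformers from %d trials (%s)%s\n",
              x$site$chain_id, x$site$residue_number, x$site$insertion_code,
              length(x$conformers), x$trials_run, x$params$thoroughness,
              if (n_sn > 0L) sprintf(", %d snuggly", n_sn) else ""))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param e A `label_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(e) length(e$conformers)

## Spin-center coordinates of every conformer, n x 3.
.spin_centers <- function(e) {
  sc <- e$conformers[[1L]]$template$spin_center_name
  t(vapply(e$conformers, function(cf) cf$coords[sc, ], numeric(3L)))
}

## Chi matrix of an ensemble, n x 5.
.chi_matrix <- function(e) {
  t(vapply(e$conformers, `[[`, numeric(5L), "chi"))
}

#' Restrict an ensemble to its snuggly-flagged conformers
#'
#' @param e A `label_ensemble` whose flags were filled by [flag_snuggly()].
#' @return A `label_ensemble` containing only flagged conformers.
#' @export
snuggly_subset <- function(e) {
  keep <- vapply(e$conformers, function(cf) isTRUE(cf$snuggly), logical(1L))
  out <- e
  out$conformers <- e$conformers[keep]
  out$subset_label <- "snuggly"
  out
}
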