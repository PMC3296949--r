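# contact_scoring: the "snuggly fit" surface-complementarity heuristic.
# For a non-clashing conformer, count the protein atoms that sit outside
# the vdW cutoff but within a 4.5 A shell of any label atom; conformers
# reaching at least 75% of the ensemble maximum are flagged.  The score
# merely flags candidates seated in surface pockets for the scientist to
# inspect -- it is not an energy.

#' Parameters of the snuggly-fit contact score
#'
#' @param shell_radius Outer shell radius in Angstrom (default 4.5).
#' @param flag_fraction Fraction of the ensemble-maximum contact count at
#'   or above which a conformer is flagged (default 0.75).
#' @param requires_painstaking Require the ensemble to come from a
#'   painstaking search (default `TRUE`): at lower thoroughness the
#'   conformational space is not sampled well enough for the maximum to be
#'   meaningful.
#' @return A `contact_params` object.
#' @export
contact_params <- function(shell_radius = 4.5, flag_fraction = 0.75,
                           requires_painstaking = TRUE) {
  stopifnot(flag_fraction > 0, flag_fraction <= 1, shell_radius > 0)
  structure(list(shell_radius = shell_radius,
                 flag_fraction = flag_fraction,
                 requires_painstaking = requires_painstaking),
            class = "contact_params")
}

## Distinct environment atoms whose minimum distance to any clash-tested
## label atom lies in [cutoff, shell] (both ends inclusive: an atom at
## exactly the vdW cutoff is a contact, not a clash).
.count_contacts <- function(label_xyz, env_xyz, cutoff, shell) {
  if (nrow(env_xyz) == 0L) return(0L)
  d2 <- .dist2_matrix(env_xyz, label_xyz)
  mind2 <- do.call(pmin, as.data.frame(d2))
  sum(mind2 >= cutoff^2 & mind2 <= shell^2)
}

#' Count shell contacts of a conformer
#'
#' @param c A `label_conformer` (should be non-clashing).
#' @param env Environment atoms (`spatial_index`, atom data.frame or
#'   coordinate matrix).
#' @param vdw_cutoff Inner radius (the clash cutoff), Angstrom.
#' @param shell Outer shell radius, Angstrom; must exceed `vdw_cutoff`.
#' @return Integer number of distinct environment atoms with minimum
#'   label-atom distance in `[vdw_cutoff, shell]`.
#' @export
contact_count <- function(c, env, vdw_cutoff = 3.4, shell = 4.5) {
  stopifnot(inherits(c, "label_conformer"), shell > vdw_cutoff)
  label_xyz <- c$coords[c$template$side_chain_names, , drop = FALSE]
  .count_contacts(label_xyz, .env_coords(env), vdw_cutoff, shell)
}

#' Flag snuggly-fitting conformers of an ensemble
#'
#' Computes the contact count of every conformer, takes the ensemble
#' maximum M and flags each conformer whose count is at least
#' `flag_fraction * M`.  With a non-empty ensemble and M > 0 at least one
#' conformer (the maximum) is always flagged; when M = 0 none is.
#'
#' @param e A `label_ensemble` (painstaking thoroughness unless
#'   `p$requires_painstaking` is `FALSE`).
#' @param env Environment atoms of the labeled structure, e.g.
#'   `environment_for_site(s, e$site)`; a `spatial_index`, atom data.frame
#'   or coordinate matrix.
#' @param p A [contact_params()] object.
#' @return The ensemble with `contact_count` and `snuggly` filled in on
#'   every conformer.
#' @export
flag_snuggly <- function(e, env, p = contact_params()) {
  stopifnot(inherits(e, "label_ensemble"), inherits(p, "contact_params"))
  if (p$requires_painstaking && e$params$thoroughness != "painstaking") {
    stop("snuggly-fit flagging needs a painstaking search: otherwise the conformational space is not sampled well enough")
  }
  if (length(e$conformers) == 0L) return(e)
  env_xyz <- .env_coords(env)
  counts <- vapply(e$conformers, function(cf) {
    .count_contacts(cf$coords[cf$template$side_chain_names, , drop = FALSE],
                    env_xyz, e$params$vdw_cutoff, p$shell_radius)
  }, integer(1L))
  m <- max(counts)
  flags <- if (m == 0L) rep(FALSE, length(counts))
  else counts >= p$flag_fraction * m
  e$conformers <- Map(function(cf, ct, fl) {
    cf$contact_count <- ct
    cf$snuggly <- fl
    cf
  }, e$conformers, counts, flags)
  e$contact_params <- p
  e
}
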