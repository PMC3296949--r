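---
title: "Stochastic in silico spin labeling: model, parameters and design choices"
author: "spinlabelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic in silico spin labeling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinlabelr)
```

## The problem

PELDOR/DEER spectroscopy measures nanometre distances (roughly 15–80 Å)
between paramagnetic centres. Most proteins have none, so cysteines are
introduced and labeled with the MTSSL nitroxide reagent. The resulting R1
side chain places five rotatable bonds — chi1 through chi5 — between the
backbone and the unpaired electron, which sits more than 7 Å from the
C-alpha. A measured distance therefore reflects an unknown mixture of
label conformers, and interpreting it against a structural model requires
a model of where the nitroxide can be.

`spinlabelr` implements the *accessible-volume* answer to that question:
enumerate, by random sampling, every label conformer that is sterically
possible, and treat them all as equally likely. No rotamer library, no
energies, no temperature model. The deliberate assumption is that a
surface-attached label samples its whole sterically allowed space; where
the protein restricts that space (pockets, clefts), the clash test — and
optionally the surface-complementarity score — encodes the restriction.

## The search procedure

For a site (chain, residue number):

1. **Attachment.** The built-in R1 template (ideal internal geometry:
   standard bond lengths and angles; the nitroxide ring with its four
   methyls is one rigid planar unit) is superposed onto the residue's
   N/CA/CB by least squares. Glycine gets an ideal tetrahedral C-beta
   constructed from N, CA, C. The residue's own side chain plays no
   further role — mutation to R1 is implied.
2. **Sampling.** Each trial draws chi1..chi5 independently and uniformly
   on [0°, 360°). The thoroughness preset fixes the number of trials:
   painstaking 1500, thorough 300, normal 90, quick 10. This is a fixed
   budget of complete five-angle conformations, not a grid: shortening
   the search cannot systematically miss regions, it only samples them
   more sparsely.
3. **Internal clash.** A conformer is discarded if any two label atoms
   more than three bonds apart come closer than 2.0 Å. The three-bond
   exemption leaves 1–4 (gauche) proximities unpenalised; 2.0 Å forbids
   genuine atomic overlap. The cutoff is exposed as
   `internal_clash_cutoff`.
4. **External clash.** A clash is an environment atom strictly closer
   than the vdW cutoff (default 3.4 Å, a typical carbon–carbon packing
   distance) to any clash-tested label atom. One uniform cutoff is used
   for all element pairs: the ~0.3 Å spread of true vdW radii is small
   against the method's ~3.5 Å prediction error. Distinct environment
   atoms are counted once each; a conformer survives if its count does
   not exceed `allowed_clashes` (default 0, range 0–5).

Identical seeds reproduce identical ensembles; each trial consumes
exactly five random draws, which is what makes the subset-monotonicity
properties (in cutoff and in allowed clashes) exact rather than
statistical.

### The two tolerance knobs

Crystal structures are static and surface side chains are often poorly
determined, so an apparent clash in the model may not exist in solution.
Two parameters deliberately let the user trade strictness for tolerance:
`vdw_cutoff` may be lowered from 3.4 Å to 2.6 Å (a heavy-atom
hydrogen-bond distance), and `allowed_clashes` raised from 0 to 5. Both
ranges are enforced; going outside them requires `force = TRUE` and
draws a caution. When a search finds nothing, the package suggests these
remedies but never relaxes parameters on its own — that judgment belongs
to the scientist.

### What counts as environment

The clash environment is every heavy atom of the structure except the
labeled residue itself; hydrogens always, and waters and hetero atoms by
default, are excluded (the cutoff is defined in heavy-atom terms, and
ligand/solvent occupancy at a labeling site is rarely meaningful).

One further exclusion is a considered design choice of this package: the
backbone atoms (N, CA, C, O) of the two sequence-adjacent residues. They
are four to six covalent bonds from the tether, and their distance to it
is fixed by backbone geometry rather than by sterics — depending on
phi/psi, the gamma sulfur sits 2.1–3.7 Å from the i±1 backbone across
the chi1 circle. Counting those contacts against a uniform 3.4 Å cutoff
would reject conformations that spin-labeled crystal structures actually
exhibit, and would leave most exposed surface sites unlabelable at
default parameters (on the exposed tripeptide fixture, acceptance falls
from ~65% to ~3%). `exclude_adjacent_backbone = FALSE` restores the raw
environment for users who want it.

### Boundary conventions

All boundaries are single and testable: radius queries use closed balls
(d ≤ r); a clash requires strict violation (d < cutoff), so an atom at
exactly the cutoff is not a clash; the contact shell is closed on both
ends ([cutoff, 4.5 Å]); histogram bins are half-open [lo, hi), so a
value on an edge belongs to the upper bin; the snuggly threshold uses ≥.

## Snuggly-fit scoring

A label seated in a hydrophobic surface pocket may be effectively
immobilised, giving a very different distance distribution than the
free-sampling assumption predicts. As a flag — not an energy — the
package counts, for each accepted conformer, the environment atoms that
lie outside the vdW cutoff but within a 4.5 Å shell of any label atom
(each atom counted once). The conformer with the highest count, and all
conformers within 75% of that maximum, are flagged "snuggly". The shell
is taken around every label atom (union of spheres): a 4.5 Å sphere
around the label centroid would not even reach the protein surface, so
that alternative reading is rejected. Flagging requires a painstaking
search by default, because at lower sampling depth the maximum is too
noisy to anchor a relative threshold. Two known limits: the score sums
contacts indiscriminately, so it is most meaningful for hydrophobic
pockets (polar contacts have geometric requirements a count ignores),
and it flags possibilities for inspection rather than making a call.

## Distance analysis

Between two ensembles, all n_a × n_b distances between the nitroxide
nitrogens (N1) are computed — N–N, not the N–O midpoint, and with every
conformer weighted equally, so the "weighted mean" is the plain
arithmetic mean. Summaries are the mean, median, extremes, the
C-beta–C-beta reference distance, and whether the mean falls in the
15–80 Å PELDOR window. The default histogram bin width is 1 Å,
comparable to the resolution at which PELDOR distributions are usually
analysed and well below the method's ~3.5 Å accuracy; the most probable
distance is reported as the centre of the modal bin with ties broken
toward the shorter distance, so reports are deterministic. As a search-free
first guess, adding 6.5 Å to the C-beta–C-beta distance approximates the
expected inter-label distance (the C-beta baseline underestimates it by
about that much on average).

## Copy and move

For symmetric multimers only one search per unique site is needed: the
ensemble is transferred to a symmetry mate by superposing the one-residue
backbone frame (N, CA, C, O, CB; CB constructed for glycine) of the
source onto the target and applying the resulting proper rigid transform
to every conformer. The transfer is an exact isometry. By default no
clashes are re-checked — faithful "copy" semantics for exact symmetry;
`revalidate = TRUE` re-runs the clash test against the target
environment and drops violators, which is the right choice for
pseudo-symmetric assemblies. A backbone fit rmsd above 0.5 Å triggers a
warning that the sites may not be symmetry-equivalent.

## The synthetic structures

The fixture generators produce the situations the method must handle,
without any downloads, and are deterministic:

- `make_gxg_peptide()` — an extended Gly–Ala–Gly tripeptide; the middle
  residue is a maximally exposed site. A normal search accepts ~65% of
  trials there; the rejected remainder is dominated by internal clashes
  of the label (~31% of uniform chi draws fold the chain onto itself).
- `make_cone_pocket(aperture)` — a spherical shell (radius 8.5 Å around
  the site C-beta) with a conical aperture cut out: a label at the bottom
  of a conical pit. Only conformers threading the nitroxide through the
  aperture survive, so accepted counts rise monotonically with aperture
  (≈12/1500 at 40°, ≈270/1500 at 160° at painstaking depth) and the chi
  spread narrows as the aperture closes. A bare cone *surface* does not
  work as a fixture — a narrow cone blocks only a narrow solid angle and
  lets backward-pointing conformers through — which is why the cavity is
  modelled as a shell with an opening. The radius was chosen once so the
  narrowest tested aperture restricts without sealing.
- `make_wall(offset)` — a 1.5 Å-spaced plane of carbon pseudo-atoms
  facing the site; no accepted atom can come closer than the cutoff.
- `make_cage(radius)` — a closed shell around the C-beta; at 2.5 Å
  radius nothing fits and the search must return empty.
- `make_symmetric_dimer(rotation)` — two tripeptides related by an exact
  rotation about z; the reference case for copy-and-move (backbone fit
  rmsd 0) and for inter-ensemble distances.

Barrier pseudo-atoms are ordinary carbon ATOM records so the uniform
cutoff applies unchanged, and their 1.5 Å spacing keeps barriers
impervious at every sanctioned cutoff (≥ 2.6 Å).

What these fixtures do *not* emulate: real packing density and shape,
chemical heterogeneity of the environment, backbone flexibility, or
crystallographic artefacts. Tests passing on them demonstrate the
correctness of the sampling, clash, scoring and transfer machinery — not
the prediction accuracy on real proteins, which is what the
structure-based benchmark (below) addresses.

## The published-benchmark machinery

`benchmark_pairs()` ships a 52-row table of published PELDOR/CW-EPR
distances for doubly labeled T4 lysozyme (PDB 2LZM) and (H3–H4)2 histone
(PDB 1TZY), with the experimental mean/peak values, the per-pair search
settings required at the handful of tight sites (thorough depth, vdW
3.0–3.2), and the published reference predictions. Against those
reference columns the residuals reproduce the published aggregates
(mean ≈ +1.2 Å, sd ≈ 3.0 Å for the simulated label; −6.4 ± 3.5 Å for
the raw C-beta baseline — the origin of the +6.5 Å rule of thumb).
`cmd_benchmark()` recomputes the predictions from scratch when the user
supplies the two structures; nothing is downloaded, and missing files
are listed explicitly. The histone rows pair the same residue on the two
symmetry-equivalent chains; the chain letters in the table are the
package's assumption and are editable if a particular copy of the
structure is numbered differently.

## Numerical choices and degenerate inputs

- Dihedrals follow the standard sign convention (an alpha-helical phi is
  ≈ −60°) and are reported on [0°, 360°); agreement with an independent
  implementation is tested to 1e-4°.
- Torsion application is exact rigid-motion composition: template bond
  lengths, angles and chirality are invariant to 1e-9 Å under arbitrary
  chi, and apply→measure round-trips to 1e-13°.
- Superposition uses the SVD (Kabsch) solution with the determinant
  correction, so reflections can never be returned; colinear point sets
  are refused.
- Alternate locations resolve to the highest occupancy, ties to altloc
  "A"; multi-MODEL files yield their first MODEL unless another is
  requested. Both rules are stated because PDB files demand them and
  neither choice is universal.
- The spatial hash grid is exact: query results are tested against the
  O(n) scan on randomised configurations.
- Searches restore the caller's RNG state; reproducibility comes from
  the recorded per-search seed, not from global side effects.

## Problem sizes in the tests

The shipped tests run searches at quick/normal/thorough depth for the
mechanical properties and painstaking depth (1500 trials) where a
distribution or a relative threshold is asserted (cone monotonicity,
snuggly flagging, copy-move distribution agreement); the whole suite and
the analysis script each complete in well under a minute on one core.
These sizes were chosen as the smallest at which the asserted properties
are stable across seeds.

## Limitations

The method predicts the accessible volume, not the populated one: where
a label is genuinely immobilised by interactions the uniform weighting
overestimates the spread (the snuggly flag mitigates, not solves, this).
The uniform cutoff ignores element-specific radii and attraction
entirely; orientation-selective PELDOR effects and time-trace inversion
are out of scope; no crystallographic symmetry expansion is performed,
so labels near lattice contacts should be checked against the biological
assembly the user actually means.
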