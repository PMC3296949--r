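Package: spinlabelr
Title: In Silico Site-Directed Spin Labeling and PELDOR/DEER Distance
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic in silico attachment of the MTSSL nitroxide spin
    label to protein structures for the planning and interpretation of
    PELDOR/DEER distance measurements.  Conformers of the R1 side chain
    are generated by uniform random sampling of its five chi torsions and
    accepted or rejected by van-der-Waals clash tests against the protein
    environment; accepted ensembles yield all-pairs nitroxide N-N distance
    distributions, summary statistics, text histograms, the Cbeta-Cbeta
    reference distance and the +6.5 Angstrom rule-of-thumb estimate.  A
    surface-complementarity ("snuggly fit") score flags conformers seated
    in surface pockets, and computed ensembles can be transferred to
    symmetry-related sites of multimers by backbone superposition.
    Includes synthetic test structures (exposed tripeptide, cone pocket,
    wall, cage, symmetric dimer) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
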