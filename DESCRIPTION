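Package: hemefep
Title: Free Energy Profiles and Oxygen Binding-Energy Decomposition for Heme Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect ligand affinity in heme proteins such as human
    hemoglobin. Estimates ligand-migration free energy profiles from steered
    trajectories via the Jarzynski equality with bootstrap mean-square-error
    uncertainties, reconstructs distal-histidine gate-opening profiles from
    umbrella-sampling windows with a periodic WHAM solver, performs the
    oxygen binding-energy and mutant decomposition bookkeeping used with
    QM/MM energies, and computes heme-pocket geometric descriptors from PDB
    structures. A built-in overdamped Langevin simulator on model potentials
    with known analytic ground truth generates all inputs, so every stage of
    the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
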