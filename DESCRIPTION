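Package: conforma
Title: Conformational Free-Energy Landscapes and Structural Metrics for
    Nuclear-Receptor Helix 12
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise alternative helix-12 (H12) conformations
    of nuclear-receptor ligand-binding domains. Provides PDB coordinate
    handling with robust treatment of altlocs and unmodeled residues;
    pairwise conformer metrics (core-aligned region RMSD, helix displacement
    angles, charge-clamp distances, residue contact maps, geometric hydrogen
    bonds, RMSD-space landscape projection, trajectory mobility
    distributions); an adaptive-biasing-force (ABF) free-energy estimator
    with binned force accumulation, ramped bias and boundary restraints,
    exercised on analytic multi-basin channel potentials sampled by
    overdamped Langevin dynamics; and landscape analysis: multi-replica
    merging, least-squares integration of the mean-force field, basin
    detection, minimum free-energy (minimax) paths and barrier heights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
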