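Package: grappi
Title: Graph Representations of Protein-Protein Interfaces for Neural Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts two-chain protein complexes from PDB coordinate files into
    rotation-invariant residue-level interface graphs with physicochemical and
    evolutionary node features and distance-derived edge features, computes
    docking-quality target values (fraction of native contacts, interface and
    ligand RMSD, CAPRI quality classes) against reference structures, and trains
    and evaluates a two-branch graph interaction network (GINet) for regression
    or classification on interface properties. Includes ranking and
    classification metrics for scored model sets, HDF5 dataset storage, a
    synthetic fixture generator (idealized complexes, rigid-perturbation decoy
    ensembles, synthetic sequence profiles), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    rhdf5,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
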