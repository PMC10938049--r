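Package: softdock
Title: Rigid-Body Multi-Protein Docking with a Soft 8-6 Lennard-Jones
    and Coulomb Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable toolkit for exploratory rigid-body multi-body
    protein-protein docking. Reads all-atom Tripos mol2 structures with
    partial charges, scores scenes of posed molecules with a soft 8-6
    Lennard-Jones potential plus distance-scaled Coulomb electrostatics
    under a 12 Angstrom cutoff (cell-grid accelerated), refines poses by
    greedy random rigid-body perturbation, and builds grid-based
    Solvent-Excluded-Surface meshes with per-vertex electrostatic charge
    mapping and red-white-blue coloring. Includes deterministic synthetic
    fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
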