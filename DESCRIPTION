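Package: polyscape
Title: Crystal Energy Landscape Analysis for Conformational Polymorphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing crystal structure prediction (CSP) energy
    landscapes of conformationally flexible molecules. Reads and writes a
    practical subset of CIF, extracts whole molecules across periodic
    boundaries, and measures key torsion angles. Applies gas-phase monomer
    conformational-energy corrections to crystal lattice energies, builds
    ranked energy-density landscapes with packing-similarity deduplication
    (N-molecule cluster RMSD), screens polymorph stability under pressure via
    H = E + PV with Birch-Murnaghan equation-of-state support and crossover
    detection, and classifies conformational polymorph color from dihedral
    angles. A seeded synthetic-landscape generator with a controllable
    planarity bias makes every stage testable without electronic-structure
    back-ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
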