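Package: rpiglue
Title: Discovery Metrics for Protein-RNA Interface Stabilizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational layer of a virtual-screening workflow for small
    molecules that stabilize protein-RNA interactions ("molecular glues").
    Reads protein-RNA complexes from PDB files and applies structural
    screening criteria; scores interface pockets and docked ligands by
    buried surface area from an in-package Shrake-Rupley solvent-accessible
    surface area implementation; derives pocket hydration descriptors
    (convex-hull water counts, densities relative to bulk water, and the
    translational order parameter of pocket waters) from trajectories;
    runs the two-stage docking-score / second-rank buried-surface-area
    filter funnel with MMGB/SA-based stabilizer classification and a
    random-forest pocket-druggability model; analyses compound chemistry
    through circular-fingerprint fragment scoring and BRICS
    fragmentation/recombination; and quantifies agreement between ligand
    placements with center-of-mass and RMSD congruence metrics. A seeded
    synthetic-fixture generator makes every step testable without external
    engines or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    withr,
    jsonlite,
    ranger,
    pROC,
    generics
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pracma,
    optparse
Config/testthat/edition: 3
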