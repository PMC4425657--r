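Package: primedmd
Title: Discontinuous Molecular Dynamics for Coarse-Grained Peptide Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven (discontinuous) molecular dynamics for a four-sphere
    per-residue coarse-grained protein model of the PRIME20 family, aimed at
    desk-scale studies of amyloid peptide aggregation. Provides the augmented
    force field (double-well side-chain potentials, directional backbone
    hydrogen bonds with a parallel-preference cutoff set, and an enhanced
    lysine-aspartate salt bridge), a self-avoiding random-coil configuration
    generator, an exact event-driven simulation engine with an Andersen-style
    ghost-collision thermostat and linear cooling schedules, and trajectory
    statistics: backbone dihedrals, beta-strand assignment, per-residue
    strand-content profiles, solvent-accessible surface area on the
    four-sphere geometry, maximum-population (P_max) energy statistics,
    salt-bridge counts, and chain-shape classification (U/S/triangular).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    bio3d,
    optparse
Config/testthat/edition: 3
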