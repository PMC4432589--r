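Package: tmgeom
Title: Geometric Analysis of Membrane-Transporter Conformational States
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative structural analysis of alternating-access
    conformational changes in major facilitator superfamily (MFS)
    transporters, built around the nitrate/nitrite antiporter NarK.
    Provides fixed-format PDB coordinate I/O with a small atom-selection
    language, selection-restricted Kabsch superposition and RMSD,
    hinge-glycine helix bend-angle quantification, cytoplasmic gate-layer
    contact inventories (hydrophobic contacts, hydrogen bonds,
    water-mediated bridges), substrate-binding-site geometry and
    grid-flood-fill pocket volumes, trajectory statistics (RMSD series,
    per-residue RMSF, inter-bundle centroid distances), and a
    synthetic-structure generator so that every analysis stage is testable
    against planted ground truth without downloading coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
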