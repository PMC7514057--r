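Package: idpbind
Title: Two-Step Binding Pathway Analysis for Disordered Peptides and
    Protein Interaction Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the two-step binding pathway of an
    intrinsically disordered peptide to a protein interaction domain
    (unbound, encounter complex, fully engaged) from molecular dynamics
    trajectories. Provides readers for PDB topologies and DCD/multi-model
    PDB trajectories, per-frame geometric observables (binding surface
    distance, dihedral-angle RMSD, secondary-structure content),
    intermolecular interaction analysis (residue contact maps, long-range
    electrostatic and hydrophobic contacts, hydrogen bonds, salt bridges,
    solvent-accessible surface area), hysteresis-based state
    classification and encounter-complex subcategories, first-passage-time
    extraction with exponential fitting and bootstrap errors, steady-state
    two-step rate algebra, and a synthetic-data generator so every stage
    of the pipeline is testable without large simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
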