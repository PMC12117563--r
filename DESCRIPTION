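Package: fvkit
Title: Standardization, Interface Analysis and Docking-Quality Scoring of
    Antibody Variable-Region Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating antibody and antibody-antigen crystal
    structures into standardized one-complex-per-file variable-region
    records. Reads PDB and mmCIF files, applies Martin-scheme numbering
    through a pluggable engine, pairs heavy and light variable domains by
    conserved-cysteine geometry, resolves antigen oligomeric state,
    detects CDR-antigen interfaces and splits entries into per-complex
    files. Prepares docking inputs (sequential renumbering, active/passive
    restraint lists from solvent accessibility), scores docked poses
    against a reference complex with a DockQ-style metric (Fnat, interface
    RMSD, ligand RMSD) and computes a per-residue molecular descriptor
    suite (relative solvent accessibility, residue depth, protrusion
    index, half-sphere exposure, backbone dihedrals, secondary structure,
    hydrophobicity) emitted as CSV. A deterministic generator of synthetic
    antibody-like structures makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
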