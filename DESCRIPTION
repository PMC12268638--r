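Package: KinaseScape
Title: Conformational Landscapes, Domain Geometry and Ion-Site Geometry of
    Protein Kinase Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing crystallographic ensembles of protein kinase
    domains. Reads PDB/mmCIF coordinates, builds residue correspondences
    within and across homologs (author numbering or Needleman-Wunsch global
    alignment), performs Kabsch least-squares superposition and global
    Calpha RMSD, fits principal components of conformation across an aligned
    ensemble (lobe opening and interlobe twist), decomposes interdomain
    motion into rotation angles and helix-axis angle changes, and classifies
    candidate monovalent-cation sites (K+ vs Na+ vs water) from
    coordination-shell geometry. Includes a deterministic synthetic-structure
    generator (two-lobe models with controllable opening/twist, ideal
    helices, octahedral ion sites) so every stage is testable without
    downloading deposited entries, and a config-driven pipeline with CSV/JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'KinaseScape-package.R'
    'structure-io.R'
    'superpose.R'
    'conformational-pca.R'
    'domain-geometry.R'
    'ion-sites.R'
    'pipeline.R'
    'synthetic.R'
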