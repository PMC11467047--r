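Package: complexqa
Title: Interface Quality Assessment for Models of Biomolecular Complexes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the similarity of every inter-chain interface in a model
    of a biomolecular complex against a reference structure. For each
    protein-protein or protein-nucleic interface it computes the fraction of
    native contacts (fnat), the interface RMSD (iRMSD) and the ligand RMSD
    (LRMSD), and combines them into a single DockQ score in [0, 1]; scores
    are averaged over all reference interfaces into a GlobalDockQ. Chain
    assignments for symmetric multimers are found by exhaustive permutation
    within groups of sequence-identical subunits, and small-molecule ligands
    are scored by pocket-aligned RMSD minimized over symmetry-equivalent
    atom correspondences obtained by element-labeled graph matching. Reads
    PDB and mmCIF files, plain or gzip-compressed, and provides both a
    library API and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
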