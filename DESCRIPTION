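Package: allodyn
Title: Allosteric Communication Analysis for Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking ligand-binding-pocket dynamics to
    cofactor-binding-pocket dynamics in nuclear-receptor conformational
    ensembles. Provides Kabsch superposition with RMSD/RMSF profiles,
    k-means representative structures, dynamic cross-correlation matrices,
    occupancy-gated residue interaction networks with -log|C| edge weights,
    Girvan-Newman communities and optimal/suboptimal allosteric paths,
    triangle-area pocket collective variables with two-dimensional free-energy
    landscapes, hydrogen-bond distance occupancy, and per-residue
    MM/GBSA-style interaction-energy decomposition. A synthetic-ensemble
    generator with planted residue-level correlation structure supplies
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
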