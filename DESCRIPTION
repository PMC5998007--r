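Package: rintools
Title: Residue Interaction Network Centrality and Flexibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue interaction networks (RINs) from protein
    structures, including multi-model NMR ensembles and in-silico alanine
    point mutants, and compares central residues across conformers and
    mutants. Implements residue centrality analysis (RCA: change in average
    shortest path length under single-node removal), betweenness (BCA) and
    closeness (CCA) centrality analyses, each standardized to per-network
    Z-scores; integrates per-residue backbone-flexibility (S2) scores from a
    DynaMine-compatible service or a deterministic offline mock; and emits
    cross-network recap tables, visual-style attribute tables, a
    command-line interface and a small localhost command service. Includes
    deterministic synthetic-structure generators so the full pipeline runs
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
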