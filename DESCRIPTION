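Package: foldspot
Title: Spatial Hotspot Analysis and Point-Density Clustering of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory spatial analysis of protein structures at residue
    resolution. Parses and writes PDB files (including AlphaFold models with
    per-residue pLDDT in the B-factor column), builds residue neighbour
    weights (distance band, k-nearest, distance decay), detects feature
    hotspots by local spatial autocorrelation (Getis-Ord G/G* or local
    Moran's I) with conditional permutation inference and Benjamini-Hochberg
    false discovery rate control, aggregates features in a spherical sliding
    window, clusters residues in 3D with HDBSCAN-style density clustering or
    Markov clustering, exports per-residue annotation tables, and composes
    layered grammar-of-graphics scene descriptions for external molecular
    viewers. Includes deterministic synthetic structure generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
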