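Package: extspace
Title: Distances Between Extension Spaces of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the shortest Billera-Holmes-Vogtmann (BHV) distance
    between the extension spaces of two phylogenetic trees with non-identical
    leaf sets. Includes a geodesic treepath (GTP) engine for BHV geodesics,
    enumeration of connection clusters (all maximal orthants met by an
    extension space), a reduced gradient optimizer for the per-orthant-pair
    convex program, and construction of candidate supertrees as geodesic
    midpoints of optimal pairs. A simulation module generates random binary
    trees with lognormal or mixture branch lengths for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
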