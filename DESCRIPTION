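Package: connscape
Title: Circuit-Theory Genetic Connectivity Mapping and Conservation Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing landscape genetic connectivity for
    conservation. Builds a resistance graph from a landscape resistance
    raster, solves pairwise circuit problems (effective resistances and
    per-cell current maps) for the edges of an empirical genetic network,
    sums current maps into a cumulative connectivity surface, thresholds
    and delineates priority pathways, ranks spanning-tree edges by
    betweenness, computes overlay statistics against conservation polygons
    (including an equal-area random-placement baseline), and intersects
    land-cover impedance thresholds with top-connectivity landscapes to
    produce spatial action maps. Includes a synthetic-landscape generator
    with analytically solvable micro-fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
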