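Package: selfsim
Title: Spectral Self-Similarity and Small-World Analysis of Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A spectral-graph toolbox for probing undirected networks for
    fractal self-similarity and small-world structure. Assembles simple
    undirected graphs from directed chemical-synapse and symmetric
    gap-junction adjacency matrices (as for the C. elegans connectome),
    builds graph Laplacians and their degree-normalized form, and provides
    the eigenvalue counting function, Weyl ratios with fitted power-law
    exponents, spectral-gap detection, and eigen-projection coordinates.
    Includes generators for the comparison graphs used in this kind of
    analysis (Erdos-Renyi random graphs, random branching trees, level-m
    Sierpinski gasket and hexacarpet graph approximations, probabilistic
    edge rewirings, matched random graphs), small-world statistics
    (clustering coefficient, average path length) against matched random
    controls, and eigenfunction-localization measures based on graph
    energy, effective resistance and spacial variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
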