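Package: gravityrank
Title: Gravity-Model Centralities for Identifying Influential Spreaders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Node-influence ranking in undirected networks by the gravity
    model, which scores a node by summing degree-product "masses" over
    inverse squared shortest-path distances, and its local variant that
    truncates the sum at a hop radius R. Includes seven benchmark
    centralities (degree, H-index, k-shell, closeness, betweenness, and
    the k-shell-mass gravity centralities G and G+), a discrete-time SIR
    spreading simulator providing the ground-truth influence of each node,
    a tie-aware Kendall rank correlation for comparing rankings, topological
    summary statistics with the heterogeneous mean-field epidemic threshold,
    truncation-radius optimisation, and synthetic network generators with
    brute-force oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
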