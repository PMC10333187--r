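Package: chdgraph
Title: Directed-Graph Models of the Circulation and Congenital Heart Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Represents the human circulation as a labeled directed graph in
    which vertices are blood-containing spaces and edges are directed blood
    flows, with equivalent binary adjacency matrices.  Ships a declarative
    catalog of congenital heart disease (CHD) manifestations and palliative
    or corrective procedures expressed as graph edit scripts (add or remove
    vertices and edges, column interchanges for transposition physiology),
    an engine to apply and compose them, reachability-based viability
    analysis implementing the two-path survival rule, a five-category
    structural classifier of differences between hearts, diagnosis by
    matrix matching against the catalog, weighted adjacency matrices
    carrying hemodynamic edge measurements such as peak velocity, and a
    desk-scale enumerator of candidate unreported anatomies over restricted
    vertex subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
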