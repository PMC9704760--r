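Package: pathmapr
Title: Layout, Rendering and Graph Mining for Biological Pathway Maps
Version: 0.1.0
Authors@R: person("pathmapr", "developers", role = c("aut", "cre"),
    email = "pathmapr@example.org")
Description: Parses biological pathway maps in SBGNML (process description),
    SBML, GraphML and an elements-JSON dialect into a shared compound-graph
    model, runs compound-aware graph-mining queries (neighborhood, common
    stream, paths-between, paths-from-to, shortest path) and node centrality
    analyses (degree, closeness, betweenness, PageRank), computes an
    automatic nested force-directed layout, and renders styled,
    highlight-annotated SVG/PNG/JPG images plus layout JSON. Usable as a
    library, a command-line tool, and a thin HTTP service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    httpuv,
    optparse,
    stats,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    curl,
    withr
Config/testthat/edition: 3
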