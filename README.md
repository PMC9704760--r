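# pathmapr

Layout, rendering and graph mining for biological pathway maps.

Pathway databases publish mechanistic maps as SBGNML (SBGN process
description), SBML, GraphML or JSON — but turning such a file into a styled
image with a sensible automatic layout, or mining it for the sub-pathway
that actually answers a question ("what do these two proteins regulate in
common?", "what are all the near-shortest routes from this metabolite to
that one?"), normally requires stitching several tools together. pathmapr
does the whole pipeline in one package, usable as an R library, a
command-line tool, and a thin HTTP service: it is aimed at pathway-database
curators who need batch images, tool authors who need a layout backend, and
analysts mining individual maps.

## The model in brief

A pathway map is a **compound graph** `G = (V, A, F)`: a directed multigraph
`(V, A)` of typed nodes (macromolecules, simple chemicals, processes, ...)
and arcs (consumption, production, catalysis, inhibition, ...), plus a
containment forest `F` in which compartments and complexes hold other
nodes. Containment is not an arc; instead, compound-aware traversals treat
it as free connectivity: reaching `v` co-reaches its *effective closure*
(ancestors and descendants in `F`) at the same distance, and distances count
arcs only. On top of this primitive the package implements:

* **Queries** — k-bounded neighborhood; common stream (nodes reachable from
  *every* seed: common regulators upstream, common targets downstream);
  paths-between (all simple seed-to-seed links of ≤ k arcs); paths-from-to
  (all simple paths of length `L(s,t)` to `min(L(s,t)+d, k)` per
  source–target pair, `L` the compound shortest distance); single shortest
  path with lexicographic tie-breaking.
* **Centralities** — degree, harmonic closeness, Brandes betweenness,
  PageRank (damping 0.85); normalized scores can be written into node labels
  and shown as highlight thickness.
* **Layout** — a seeded draft (random + BFS rings) refined by a compound
  spring embedder (springs toward an ideal edge length, clipped
  inverse-square repulsion, gravity toward the parent compound; compound
  bounds recomputed from members each iteration), with overlap removal and
  component packing post-passes. Deterministic per seed.
* **Rendering** — SVG with per-class shapes/arrowheads and two color
  schemes (red–blue, or shades of a single base color); seed/result/link
  highlight roles in green/red/yellow; PNG/JPG by an internal rasterizer;
  optional cropping to the query result.

## Worked example

Parse a one-reaction SBML model, score it, lay it out:

```r
library(pathmapr)

rep <- read_sbml(sbml_text)   # glucose -> G6P, catalyzed by hexokinase
rep
#> <parse_report> [sbml] 5 nodes, 3 edges, 0 warning(s)

round(betweenness_centrality(rep$graph)$normalized, 2)
#>  c  A  B  E r1
#>  0  0  0  0  1
```

The reaction node `r1` is the only cut vertex between the three species, so
its normalized betweenness is 1 and everything else scores 0 (the
compartment `c` has no arcs and is excluded from the distance graph).

```r
g <- apply_geometry(rep$graph, layout_pathway(rep$graph, layout_options(seed = 42)))
cat(substr(write_layout_json(g), 1, 120))
#> {
#>   "A": {
#>     "x": 103.613169272522,
#>     "y": 19.2666297491129,
#>     "w": 40,
#>     "h": 40
#>   },
#>   ...
```

The relaxed shortest-path query on a graph whose source–target pair has
shortest distance 3 and detours of lengths 4, 5 and 6:

```r
g <- canonical_graphs()$worked_example
r <- paths_from_to(g, "s", "t", additional_d = 2)
sort(vapply(r$paths, function(p) length(p) - 1L, integer(1)))
#> [1] 3 4 5
```

With additional distance 2, exactly the paths of lengths 3, 4 and 5 are
returned — the length-6 route is beyond the relaxation.

## CLI and HTTP service

```sh
# layout + highlighted common-stream image for one map
Rscript inst/cli/pathmapr --input map.json --format json \
    --layout --query common_stream --sources A,B --image out.svg

# HTTP facade: POST /{sbgnml|sbml|graphml|json}
Rscript -e 'pathmapr::serve(8765, blocking = TRUE)' &
curl -X POST -H "Content-Type: application/json" \
     --data '{"file_content": "...", "layoutOptions": {"seed": 1}}' \
     http://127.0.0.1:8765/json
```

`--input` also accepts a directory (batch mode). Exit codes: 0 success,
1 processing error, 2 usage error.

## Package layout

* `R/pathway-graph.R` — compound-graph model and invariants
* `R/io-*.R` — SBGNML / SBML / GraphML / elements-JSON readers and writers
* `R/queries.R` — compound BFS and the mining queries
* `R/metrics.R` — centralities and label annotation
* `R/layout.R` — draft placement + spring embedder
* `R/render.R`, `R/rasterize.R` — SVG assembly and raster output
* `R/fixtures.R` — synthetic map generator and canonical oracle graphs
* `R/service.R`, `R/cli.R` — request pipeline, HTTP facade, CLI
* `vignettes/pathway-maps.Rmd` — the methods vignette (semantics, parameter
  choices, limitations)
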