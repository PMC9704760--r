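---
title: "Compound pathway maps: model, queries, layout and rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound pathway maps: model, queries, layout and rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmapr)
```

## The problem

Mechanistic pathway maps — SBGN process-description diagrams, SBML reaction
networks and their generic cousins — are *compound* graphs: beyond the arcs
connecting chemicals, proteins and process nodes, the nodes themselves nest
inside cellular compartments and molecular complexes. Most graph tooling
ignores that second structure, which matters twice: traversals should flow
through a complex the way signaling does (touching a subunit reaches the
complex and, through it, the other subunits), and layout must place members
inside the container that owns them.

pathmapr models both structures explicitly and provides, on top of the
shared model: format readers and writers, compound-aware graph-mining
queries, node centralities, an automatic nested layout, styled SVG/raster
rendering with query-result highlighting, a CLI, and a small HTTP facade.

## The compound graph model

A `pathway_graph` is a directed multigraph (parallel arcs and self-loops
allowed, as SBML reactions can produce both) plus a containment *forest*.
Containment is deliberately **not** an edge: SBGN nesting is spatial and
semantic, not an interaction, so arc-based algorithms (centralities, plain
reachability) see only explicit arcs. Only the compound-aware traversals
consult the forest. Compartments and complexes are the only classes allowed
to contain; this is validated on every mutation, as is acyclicity of the
parent links.

Coordinates follow the SVG convention throughout: `(x, y)` is the node
*center*, y grows downward, sizes are in px. SBGNML bounding boxes (top-left
corner per that standard) are converted on read and back on write so there
is exactly one internal convention.

## Traversal semantics: the effective closure

The queries rest on one primitive, `compound_bfs()`. Reaching a node during
a traversal co-reaches its *effective closure* — itself, its containment
ancestors and its descendants — at zero cost; distances count arcs only.
Formally the implementation runs a layered 0/1 BFS on the expanded graph in
which every parent–child link is a pair of zero-weight directed connections.
A consequence worth spelling out: closures saturate transitively. Reaching a
complex subunit co-reaches the complex (zero cost), whose own closure
co-reaches the sibling subunits, still at distance zero. `effective_closure()`
itself reports only the ancestor/descendant set — siblings arrive through
the parent in the traversal, not through the closure operator — and the test
suite pins both behaviors, including equivalence with an independent
0/1-weight Dijkstra on the expanded graph (via igraph).

Direction is a user choice on every query: `downstream` follows arcs,
`upstream` reverses them, `both` ignores orientation (for the common-stream
query, `both` is the union of the upstream-common and downstream-common
runs, which keeps each run's semantics intact).

## The mining queries

* `neighborhood()` — parallel compound BFS from a seed set; everything
  within `limit_k` arcs joins the result, along with the traversed arcs.
* `common_stream()` — nodes reachable within `limit_k` from **every** seed:
  common targets (downstream) or common regulators (upstream). The result
  partitions into three disjoint display roles: seeds, common nodes, and the
  connecting links (arcs and intermediate nodes on any qualifying
  seed-to-common path). An arc u→v is a connecting link iff
  `min_s dist_s(u) + 1 + rdist(v) <= k`, where `rdist` is the reverse
  distance to the common set — computed with two BFS sweeps rather than path
  enumeration, so it stays polynomial.
* `paths_between()` — all simple directed paths of at most `k` arcs between
  two *distinct* seeds with no third seed as an intermediate. Paths through
  another seed are deliberately excluded: such a route is the concatenation
  of two shorter links, so admitting it would only duplicate information.
* `paths_from_to()` — for every ordered source–target pair, all simple
  paths of length between the pair's shortest distance `L` and
  `min(L + d, k)`. The relaxation `d` applies per pair, not to the global
  minimum over all pairs, matching the one-source-one-target reading of the
  contract: with `L = 3` and `d = 2`, lengths 3, 4 and 5 qualify.
* `shortest_path()` — a single shortest compound path; ties are broken by
  the lexicographically smallest node-id sequence, found by a pruned DFS
  that explores consistent successors in id order (the first complete path
  found is therefore the lexicographic minimum, with backtracking covering
  the rare dead ends that the simple-path constraint creates inside
  zero-cost containment regions).

Path length always counts arcs; containment hops are free everywhere, which
is the only reading under which the worked relaxation example comes out as
stated. Enumeration queries abort with an explicit error beyond a
configurable cap (default 10,000 paths) — path counts are exponential in
dense maps and silent truncation would be worse than failure.

```{r}
g <- canonical_graphs()$worked_example   # s->t paths of lengths 3..6
r <- paths_from_to(g, "s", "t", additional_d = 2)
sort(vapply(r$paths, function(p) length(p) - 1L, integer(1)))
```

## Centralities

Degree, harmonic closeness, betweenness (Brandes) and PageRank (power
iteration, damping 0.85, dangling mass redistributed uniformly). Choices
worth recording:

* All distance-based measures use the **undirected** view of the arcs;
  PageRank respects direction. The contract gives no directive; this matches
  the defaults of the mainstream graph libraries the original service
  delegates to.
* Closeness uses the **harmonic** form, so the disconnected maps that real
  pathway data constantly produces still yield finite scores; it is
  normalized by `n − 1`.
* Betweenness excludes endpoints and is normalized by `(n − 1)(n − 2)/2`.
* Pure containers — compound nodes without incident arcs — are excluded
  from the distance/walk graph and score 0: containment is not adjacency.
  `n` above counts participating nodes.
* The "maximum normalized value is 1" property holds exactly for the
  max-scaled measures (degree, PageRank); closeness and betweenness use
  structural denominators, so their maxima reach 1 only on the extremal
  topologies (chain middle, star center) their closed-form tests exercise.

`annotate_with_centrality()` rewrites labels ("TP53" → "TP53 (0.46)", two
decimals) and stores the normalized score as a highlight thickness that the
renderer maps linearly onto a stroke-width range — the higher the score, the
thicker the highlight.

## Layout

`layout_pathway()` is a draft-plus-refinement compound spring embedder. The
full constraint machinery of modern compound layouts (spectral drafts,
user-pinned placements, alignment constraints) is intentionally out of
scope; the option parser rejects constraint keys explicitly rather than
ignoring them.

*Draft*: seeded random placement in a √n-scaled square, siblings jittered
around a per-containment-tree cluster center, followed by one BFS pass over
the arcs that rings newly discovered neighbors around their discoverer at
the ideal edge length. Ring angles are independently randomized: evenly
spaced rings put neighbor pairs diametrically opposite, a collinear saddle
point the symmetric forces cannot escape (a triangle laid out that way
stays a line). With `randomize = FALSE`, nodes with input coordinates keep
them and only coordinate-less nodes are drafted.

*Refinement*: per iteration, springs pull arc endpoints toward
`ideal_edge_length` (spring constant 0.3 — chosen so the stop criterion
triggers near force equilibrium; with a weaker spring the convergence
threshold is crossed while the system is still visibly off balance),
clipped inverse-square repulsion acts between all movable pairs, and
gravity pulls members toward their sibling-group center. Compound bounds
are recomputed from their members every iteration, so the containment
guarantee (member rectangle inside parent minus `compound_padding`) holds
by construction rather than by constraint solving. Displacement is capped
by a cooling schedule that decays linearly from the ideal edge length to
1 px; iteration stops at `max_iterations` (default 2500) or when total
displacement drops under `convergence_threshold` (default 1 px). Two
deterministic post-passes finish the job: overlapping sibling leaves are
pushed apart, and disconnected components are packed side by side.

Determinism: all randomness flows from `layout_options(seed = )` through a
private RNG stream, so identical inputs give identical geometry and the
caller's RNG state is never touched.

## Rendering

`render_svg()` emits exactly one shape element per node and one path per
edge; compounds are drawn beneath their members (containment preorder), and
labels go on top, ellipsis-truncated at 90% of the node width. Arrowheads
are class-specific (production: filled arrow; catalysis: open circle;
inhibition: bar; stimulation: open arrow; consumption: none) and edge
endpoints are clipped to the node border so arrowheads touch shapes. Two
color schemes exist: `red_blue` (red simple chemicals, blue macromolecules)
and `single_color`, which derives per-class shades from a base color via a
declared lightness-step table. Highlight roles default to green seeds, red
result nodes and yellow links, all overridable; highlighting only restyles
existing elements, so an empty highlight renders byte-identically to none.
`result_only = TRUE` shrinks the viewBox to the highlighted elements plus
margin.

Raster output deserves a note: no SVG rasterizer library is assumed.
`rasterize()` interprets the specific SVG subset `render_svg()` produces and
redraws it on R's cairo `png()`/`jpeg()` devices, honoring the requested
dimensions by letterboxing and transparency for PNG (JPG gets a white
background plus a warning). Arrowhead markers are approximated in raster
output; SVG remains the reference rendering.

## Synthetic data

`generate_pathway()` produces SBGN-like maps: entities (alternating
macromolecules and simple chemicals) connect only through process nodes via
consumption/production arcs with occasional modulation, entities and
complexes are distributed over compartments, and each complex holds at
least two members. Sizes default to the 40×40 px entity box common in SBGN
editors. Generation is a pure function of `fixture_spec()` (counts + seed).
What the generator deliberately does **not** emulate: biological realism of
the topology (no degree distributions, no motif structure), SBGN decorations
(state variables, clone markers, ports), and stoichiometry. A green test on
generated maps therefore establishes structural correctness of the
algorithms, not fidelity to any real pathway. `canonical_graphs()`
complements it with engineered instances whose properties (shortest
distance 3 with detours 4–6; exactly two routes of lengths 4 and 6 between
two chemicals) are re-verified by enumeration at build time.

## Numerical and degenerate-input choices

* Distances are exact integers (BFS layers), so no tolerance questions
  arise in the queries; layout assertions use 1e-6 slack for float noise.
* PageRank converges on an L1 change below 1e-8 or 100 iterations.
* Empty graphs round-trip through every writer/reader pair; an empty map
  renders to a valid background-only SVG.
* SBML reversible reactions are read as irreversible in the stated
  direction with a warning — query direction semantics need one
  orientation, and the source formats give no better signal. Unknown glyph,
  arc or class names never abort a parse; they degrade to `generic` with a
  warning collected in the parse report.
* The SBML *writer* (fixture emission) targets Level 2 Version 4, because
  L2's `outside` attribute is the only core-SBML way to express compartment
  nesting; complexes are encoded as compartments tagged with the
  non-covalent-complex SBO term and recovered as complex nodes on read. The
  *reader* accepts L2 and L3, including L3 layout-package coordinates.

## Known limitations

* SBGN ports, state variables, units of information and clone markers are
  not first-class; labels may absorb them.
* Bezier edge routing is not implemented; edges are straight segments.
* Writing layout back into SBGNML/SBML/GraphML is not supported (layout is
  returned as JSON); only the elements-JSON writer embeds positions.
* The HTTP facade is single-threaded and unauthenticated by design — a thin
  programmatic surface, not a deployment-grade server.
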