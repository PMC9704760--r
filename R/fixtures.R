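# Run code with a private, seeded RNG stream, leaving the caller's RNG
# state untouched.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fixture specification for the synthetic pathway generator
#'
#' @param n_entities Number of entity nodes (macromolecules and simple
#'   chemicals, alternating).
#' @param n_processes Number of process nodes; entities connect only through
#'   processes, mimicking SBGN process-description bipartiteness.
#' @param n_compartments Number of cellular compartments; entities,
#'   complexes and processes are distributed among them.
#' @param n_complexes Number of molecular complexes; each groups at least two
#'   entities.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_entities, n_processes, n_compartments = 0L,
                         n_complexes = 0L, seed = 1L) {
  stopifnot(n_entities >= 0, n_processes >= 0, n_compartments >= 0,
            n_complexes >= 0)
  if (n_complexes > 0 && n_entities < 2 * n_complexes) {
    stop("each complex needs at least 2 entities", call. = FALSE)
  }
  structure(list(n_entities = as.integer(n_entities),
                 n_processes = as.integer(n_processes),
                 n_compartments = as.integer(n_compartments),
                 n_complexes = as.integer(n_complexes),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic pathway map
#'
#' Produces a deterministic SBGN-PD-like compound graph: entities connect
#' only through process nodes (consumption into, production out of, plus
#' occasional modulation), entities and complexes sit inside compartments
#' when compartments exist, and some entities are grouped into complexes.
#' Every node receives grid geometry so the map renders without a layout
#' pass. Topologies are structurally valid but make no claim of biological
#' realism.
#'
#' @param spec A [fixture_spec()].
#' @return A `pathway_graph`.
#' @export
generate_pathway <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_private_seed(spec$seed, {
    g <- pathway_graph()
    comp_ids <- if (spec$n_compartments > 0) {
      sprintf("comp%d", seq_len(spec$n_compartments))
    } else character(0)
    for (i in seq_along(comp_ids)) {
      g <- add_node(g, comp_ids[i], label = sprintf("compartment %d", i),
                    class = "compartment")
    }
    pick_comp <- function() {
      if (length(comp_ids)) sample(comp_ids, 1) else NULL
    }
    cx_ids <- if (spec$n_complexes > 0) {
      sprintf("cx%d", seq_len(spec$n_complexes))
    } else character(0)
    for (i in seq_along(cx_ids)) {
      g <- add_node(g, cx_ids[i], label = sprintf("complex %d", i),
                    class = "complex", parent = pick_comp())
    }
    ent_ids <- if (spec$n_entities > 0) {
      sprintf("ent%d", seq_len(spec$n_entities))
    } else character(0)
    # first 2 entities per complex become its members
    member_of <- stats::setNames(rep(NA_character_, length(ent_ids)), ent_ids)
    if (length(cx_ids)) {
      member_of[seq_len(2 * length(cx_ids))] <-
        rep(cx_ids, each = 2)
    }
    for (i in seq_along(ent_ids)) {
      cls <- if (i %% 2 == 0) "simple_chemical" else "macromolecule"
      parent <- if (!is.na(member_of[i])) member_of[[i]] else pick_comp()
      g <- add_node(g, ent_ids[i], label = sprintf("entity %d", i),
                    class = cls, parent = parent)
    }
    proc_ids <- if (spec$n_processes > 0) {
      sprintf("proc%d", seq_len(spec$n_processes))
    } else character(0)
    eid <- 0L
    for (i in seq_along(proc_ids)) {
      g <- add_node(g, proc_ids[i], label = proc_ids[i], class = "process")
      if (length(ent_ids) >= 2) {
        nin <- sample(1:min(2, length(ent_ids) - 1), 1)
        ins <- sample(ent_ids, nin)
        outs <- sample(setdiff(ent_ids, ins),
                       sample(1:min(2, length(ent_ids) - nin), 1))
        for (s in ins) {
          eid <- eid + 1L
          g <- add_edge(g, sprintf("edge%d", eid), s, proc_ids[i],
                        class = "consumption")
        }
        for (s in outs) {
          eid <- eid + 1L
          g <- add_edge(g, sprintf("edge%d", eid), proc_ids[i], s,
                        class = "production")
        }
        rest <- setdiff(ent_ids, c(ins, outs))
        if (length(rest) && stats::runif(1) < 0.3) {
          m <- sample(rest, 1)
          eid <- eid + 1L
          g <- add_edge(g, sprintf("edge%d", eid), m, proc_ids[i],
                        class = "modulation")
        }
      }
    }
    # grid geometry for leaves; compound bounds derived from members
    leaves <- node_ids(g)[vapply(g$nodes, function(n) {
      !(n$class %in% COMPOUND_CLASSES)
    }, logical(1))]
    ncol <- max(1L, ceiling(sqrt(length(leaves))))
    for (i in seq_along(leaves)) {
      row <- (i - 1) %/% ncol
      col <- (i - 1) %% ncol
      g <- set_geometry(g, leaves[i], x = 60 + col * 100, y = 60 + row * 80,
                        w = 40, h = 40)
    }
    g <- size_compounds(g, padding = 10)
    validate_pathway_graph(g)
  })
}

# Give every compound node the bounding box of its descendants plus padding
# (empty compounds get a default box).
size_compounds <- function(graph, padding = 10) {
  depth <- function(id) length(ancestors(graph, id))
  comps <- node_ids(graph)[vapply(graph$nodes, function(n) {
    n$class %in% COMPOUND_CLASSES
  }, logical(1))]
  for (id in comps[order(-vapply(comps, depth, numeric(1)))]) {
    kids <- graph$children[[id]]
    kids <- kids[vapply(kids, function(k) !is.null(graph$nodes[[k]]$geometry),
                        logical(1))]
    if (!length(kids)) {
      if (is.null(graph$nodes[[id]]$geometry)) {
        graph <- set_geometry(graph, id, 0, 0, 60, 60)
      }
      next
    }
    boxes <- lapply(kids, function(k) graph$nodes[[k]]$geometry)
    x1 <- min(vapply(boxes, function(b) b$x - b$w / 2, numeric(1))) - padding
    y1 <- min(vapply(boxes, function(b) b$y - b$h / 2, numeric(1))) - padding
    x2 <- max(vapply(boxes, function(b) b$x + b$w / 2, numeric(1))) + padding
    y2 <- max(vapply(boxes, function(b) b$y + b$h / 2, numeric(1))) + padding
    graph <- set_geometry(graph, id, (x1 + x2) / 2, (y1 + y2) / 2,
                          x2 - x1, y2 - y1)
  }
  graph
}

#' Emit a pathway graph in all four supported formats
#'
#' Writes `pathway.sbgn`, `pathway.sbml`, `pathway.graphml` and
#' `pathway.json` under `directory`; each file re-parses to a graph
#' isomorphic to the input (same node and edge multisets by label, class and
#' parent label).
#'
#' @param graph A `pathway_graph`.
#' @param directory Output directory (created if needed).
#' @param basename File stem, default `"pathway"`.
#' @return Named character vector of the four file paths, invisibly.
#' @export
emit_all_formats <- function(graph, directory, basename = "pathway") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sbgnml = file.path(directory, paste0(basename, ".sbgn")),
    sbml = file.path(directory, paste0(basename, ".sbml")),
    graphml = file.path(directory, paste0(basename, ".graphml")),
    json = file.path(directory, paste0(basename, ".json"))
  )
  writeLines(write_sbgnml(graph), paths[["sbgnml"]])
  writeLines(write_sbml(graph), paths[["sbml"]])
  writeLines(write_graphml(graph), paths[["graphml"]])
  writeLines(write_elements_json(graph), paths[["json"]])
  invisible(paths)
}

# Build a flat graph from terse edge lists: c("A->B", "B->C").
graph_from_arrows <- function(arrows, extra_nodes = character(0),
                              edge_class = "generic") {
  g <- pathway_graph()
  parts <- strsplit(arrows, "->", fixed = TRUE)
  ids <- unique(c(unlist(parts), extra_nodes))
  for (id in ids) g <- add_node(g, id)
  for (i in seq_along(parts)) {
    g <- add_edge(g, sprintf("e%d", i - 1L), parts[[i]][1], parts[[i]][2],
                  class = edge_class)
  }
  g
}

#' Canonical oracle graphs
#'
#' A fixed family of small graphs with known properties, used throughout the
#' test suite and by the acceptance checks:
#' \describe{
#'   \item{star4}{center `S` with arcs to leaves `L1..L4`.}
#'   \item{path3 / path4}{directed chains `A->B->C(->D)`.}
#'   \item{cycle3}{3-cycle `A->B->C->A`.}
#'   \item{k3 / k4}{complete graphs (one arc per unordered pair).}
#'   \item{nest3}{compartment containing a complex containing two
#'     macromolecules, plus an arc from the complex to an external node.}
#'   \item{two_route}{two vertex-disjoint directed routes (lengths 4 and 6)
#'     between two simple chemicals, the only simple paths of length <= 7.}
#'   \item{worked_example}{source `s` and target `t` joined by
#'     vertex-disjoint simple paths of lengths 3, 4, 5 and 6; shortest
#'     distance verified to be 3 at build time.}
#' }
#'
#' @return Named list of `pathway_graph` objects.
#' @export
canonical_graphs <- function() {
  star4 <- graph_from_arrows(c("S->L1", "S->L2", "S->L3", "S->L4"))
  path3 <- graph_from_arrows(c("A->B", "B->C"))
  path4 <- graph_from_arrows(c("A->B", "B->C", "C->D"))
  cycle3 <- graph_from_arrows(c("A->B", "B->C", "C->A"))
  k3 <- graph_from_arrows(c("A->B", "A->C", "B->C"))
  k4 <- graph_from_arrows(c("A->B", "A->C", "A->D", "B->C", "B->D", "C->D"))

  nest3 <- pathway_graph()
  nest3 <- add_node(nest3, "comp", label = "cytosol", class = "compartment")
  nest3 <- add_node(nest3, "cx", label = "dimer", class = "complex",
                    parent = "comp")
  nest3 <- add_node(nest3, "m1", label = "sub A", class = "macromolecule",
                    parent = "cx")
  nest3 <- add_node(nest3, "m2", label = "sub B", class = "macromolecule",
                    parent = "cx")
  nest3 <- add_node(nest3, "Z", label = "target", class = "macromolecule")
  nest3 <- add_edge(nest3, "e0", "cx", "Z", class = "stimulation")

  # Fig-5-like topology: two distinct directed chemical-to-chemical links
  two_route <- pathway_graph()
  two_route <- add_node(two_route, "s", label = "ornithine",
                        class = "simple_chemical")
  two_route <- add_node(two_route, "t", label = "arginine",
                        class = "simple_chemical")
  r1 <- c("p1", "c1", "p2")                 # s -> p1 -> c1 -> p2 -> t  (4)
  r2 <- c("p3", "c2", "p4", "c3", "p5")     # length-6 route
  for (i in seq_along(r1)) {
    two_route <- add_node(two_route, r1[i],
                          class = if (i %% 2) "process" else "simple_chemical")
  }
  for (i in seq_along(r2)) {
    two_route <- add_node(two_route, r2[i],
                          class = if (i %% 2) "process" else "simple_chemical")
  }
  link_chain <- function(g, chain, prefix) {
    for (i in seq_len(length(chain) - 1)) {
      g <- add_edge(g, sprintf("%s%d", prefix, i), chain[i], chain[i + 1],
                    class = if (i %% 2) "consumption" else "production")
    }
    g
  }
  two_route <- link_chain(two_route, c("s", r1, "t"), "ra")
  two_route <- link_chain(two_route, c("s", r2, "t"), "rb")

  # paths-from-to worked example: vertex-disjoint s->t paths, lengths 3..6
  worked <- pathway_graph()
  worked <- add_node(worked, "s")
  worked <- add_node(worked, "t")
  eid <- 0L
  for (len in 3:6) {
    mids <- sprintf("v%d_%d", len, seq_len(len - 1))
    for (m in mids) worked <- add_node(worked, m)
    chain <- c("s", mids, "t")
    for (i in seq_len(length(chain) - 1)) {
      eid <- eid + 1L
      worked <- add_edge(worked, sprintf("w%d", eid), chain[i], chain[i + 1])
    }
  }
  # build-time sanity assertions on the engineered properties
  stopifnot(compound_bfs(worked, "s")[["t"]] == 3L)
  stopifnot(length(paths_between(two_route, c("s", "t"), limit_k = 7)$paths)
            == 2L)

  list(star4 = star4, path3 = path3, path4 = path4, cycle3 = cycle3,
       k3 = k3, k4 = k4, nest3 = nest3, two_route = two_route,
       worked_example = worked)
}
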