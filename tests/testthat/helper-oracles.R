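# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately share no code with the R/ implementation:
# plain adjacency-list BFS, exhaustive recursion, and igraph where a mature
# third-party result is the reference.

# adjacency list (edge-id-free) for a flat directed graph
oracle_adjacency <- function(graph, direction) {
  ids <- node_ids(graph)
  adj <- setNames(lapply(ids, function(i) character(0)), ids)
  for (e in graph$edges) {
    if (direction %in% c("downstream", "both")) {
      adj[[e$source]] <- c(adj[[e$source]], e$target)
    }
    if (direction %in% c("upstream", "both")) {
      adj[[e$target]] <- c(adj[[e$target]], e$source)
    }
  }
  adj
}

# textbook multi-source BFS (no compounds)
oracle_bfs <- function(graph, sources, direction = "downstream",
                       limit_k = Inf) {
  adj <- oracle_adjacency(graph, direction)
  dist <- setNames(rep(0L, length(sources)), sources)
  frontier <- sources
  d <- 0L
  while (length(frontier) && d < limit_k) {
    nxt <- setdiff(unique(unlist(adj[frontier])), names(dist))
    d <- d + 1L
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# exhaustive simple-path enumeration by plain recursion (no compounds)
oracle_simple_paths <- function(graph, from, to, max_len,
                                direction = "downstream",
                                forbidden_intermediate = character(0)) {
  adj <- oracle_adjacency(graph, direction)
  out <- list()
  recurse <- function(path) {
    cur <- path[length(path)]
    if (cur == to && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    if (length(path) - 1 >= max_len) return()
    if (cur != path[1] && cur %in% forbidden_intermediate) return()
    for (nb in adj[[cur]]) {
      if (!nb %in% path) recurse(c(path, nb))
    }
  }
  recurse(from)
  out
}

# igraph view of a flat pathway graph (multigraph, directed)
to_igraph <- function(graph, directed = TRUE) {
  el <- do.call(rbind, lapply(graph$edges, function(e) c(e$source, e$target)))
  ig <- igraph::make_empty_graph(n = 0, directed = directed)
  ig <- igraph::add_vertices(ig, n_nodes(graph), name = node_ids(graph))
  if (!is.null(el)) ig <- igraph::add_edges(ig, t(el))
  ig
}

# igraph over the containment-expanded graph: arcs weight 1, containment
# links weight 0 both ways; compound distances = weighted shortest paths
to_igraph_expanded <- function(graph, direction = "downstream") {
  edges <- character(0); w <- numeric(0)
  for (e in graph$edges) {
    if (direction %in% c("downstream", "both")) {
      edges <- c(edges, e$source, e$target); w <- c(w, 1)
    }
    if (direction %in% c("upstream", "both")) {
      edges <- c(edges, e$target, e$source); w <- c(w, 1)
    }
  }
  for (n in graph$nodes) {
    if (!is.na(n$parent)) {
      edges <- c(edges, n$id, n$parent, n$parent, n$id)
      w <- c(w, 0, 0)
    }
  }
  ig <- igraph::make_empty_graph(directed = TRUE)
  ig <- igraph::add_vertices(ig, n_nodes(graph), name = node_ids(graph))
  if (length(edges)) {
    ig <- igraph::add_edges(ig, edges)
    igraph::E(ig)$weight <- w
  }
  ig
}

oracle_compound_distances <- function(graph, sources,
                                      direction = "downstream") {
  ig <- to_igraph_expanded(graph, direction)
  d <- igraph::distances(ig, v = sources, mode = "out",
                         weights = igraph::E(ig)$weight,
                         algorithm = "dijkstra")
  apply(d, 2, min)
}

# seeded random flat multigraph
random_flat_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  g <- pathway_graph()
  ids <- sprintf("n%02d", seq_len(n_nodes))
  for (id in ids) g <- add_node(g, id)
  for (i in seq_len(n_edges)) {
    uv <- sample(ids, 2, replace = TRUE)
    g <- add_edge(g, sprintf("e%d", i), uv[1], uv[2])
  }
  g
}

# seeded random compound graph: a forest of compartments/complexes plus arcs
random_compound_graph <- function(n_leaves, n_compounds, n_edges, seed) {
  set.seed(seed)
  g <- pathway_graph()
  comp_ids <- if (n_compounds > 0) sprintf("c%02d", seq_len(n_compounds))
              else character(0)
  for (i in seq_along(comp_ids)) {
    parent <- if (i > 1 && runif(1) < 0.4) sample(comp_ids[seq_len(i - 1)], 1)
              else NULL
    g <- add_node(g, comp_ids[i],
                  class = sample(c("compartment", "complex"), 1),
                  parent = parent)
  }
  leaf_ids <- sprintf("n%02d", seq_len(n_leaves))
  for (id in leaf_ids) {
    parent <- if (length(comp_ids) && runif(1) < 0.6) sample(comp_ids, 1)
              else NULL
    g <- add_node(g, id, class = "macromolecule", parent = parent)
  }
  all_ids <- c(leaf_ids, comp_ids)
  for (i in seq_len(n_edges)) {
    uv <- sample(all_ids, 2, replace = TRUE)
    g <- add_edge(g, sprintf("e%d", i), uv[1], uv[2])
  }
  g
}

path_len <- function(result_path, graph) {
  # arc count of a path returned by the package (containment hops are free):
  # count consecutive pairs joined by an actual arc
  arcs <- vapply(seq_len(length(result_path) - 1), function(i) {
    a <- result_path[i]; b <- result_path[i + 1]
    any(vapply(graph$edges, function(e) {
      (e$source == a && e$target == b) || (e$source == b && e$target == a)
    }, logical(1)))
  }, logical(1))
  sum(arcs)
}

path_signature <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"))
}

expect_same_graph <- function(a, b) {
  expect_setequal(node_ids(a), node_ids(b))
  for (id in node_ids(a)) {
    na <- get_node(a, id); nb <- get_node(b, id)
    expect_identical(na$label, nb$label)
    expect_identical(na$class, nb$class)
    expect_identical(na$parent, nb$parent)
  }
  sig <- function(g) sort(unname(vapply(g$edges, function(e) {
    paste(e$source, e$target, e$class)
  }, character(1))))
  expect_identical(sig(a), sig(b))
}

# isomorphism by label/class/parent-label multisets (ids may differ)
expect_isomorphic_maps <- function(a, b) {
  node_sig <- function(g) sort(unname(vapply(g$nodes, function(n) {
    parent_label <- if (is.na(n$parent)) "" else g$nodes[[n$parent]]$label
    paste(n$label, n$class, parent_label, sep = "|")
  }, character(1))))
  edge_sig <- function(g) sort(unname(vapply(g$edges, function(e) {
    paste(g$nodes[[e$source]]$label, g$nodes[[e$target]]$label, e$class,
          sep = "|")
  }, character(1))))
  expect_identical(node_sig(a), node_sig(b))
  expect_identical(edge_sig(a), edge_sig(b))
}
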