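CENTRALITY_MEASURES <- c("degree", "closeness", "betweenness", "pagerank")

new_centrality_report <- function(measure, raw, normalized) {
  structure(list(measure = measure, raw = raw, normalized = normalized),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat(sprintf("<centrality_report> %s over %d nodes (max raw %.4g)\n",
              x$measure, length(x$raw),
              if (length(x$raw)) max(x$raw) else NA_real_))
  invisible(x)
}

# Nodes taking part in the distance/walk graph: everything except pure
# containers (compound nodes without incident arcs). Containment is not
# adjacency, so a compartment that only holds members contributes no
# distances and scores 0.
participating_nodes <- function(graph) {
  ids <- node_ids(graph)
  has_arc <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (e in graph$edges) {
    has_arc[e$source] <- TRUE
    has_arc[e$target] <- TRUE
  }
  keep <- vapply(graph$nodes, function(n) {
    !(n$class %in% COMPOUND_CLASSES) || has_arc[[n$id]]
  }, logical(1))
  ids[keep]
}

# Simple undirected adjacency (parallel arcs collapsed, self-loops dropped)
# restricted to participating nodes; used for distance-based centralities.
undirected_adjacency <- function(graph, ids) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  seen <- new.env(parent = emptyenv())
  for (e in graph$edges) {
    if (e$source == e$target) next
    if (!(e$source %in% ids) || !(e$target %in% ids)) next
    key <- paste(min(e$source, e$target), max(e$source, e$target))
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    adj[[e$source]] <- c(adj[[e$source]], e$target)
    adj[[e$target]] <- c(adj[[e$target]], e$source)
  }
  adj
}

zero_report <- function(graph, measure) {
  ids <- node_ids(graph)
  z <- stats::setNames(numeric(length(ids)), ids)
  new_centrality_report(measure, z, z)
}

#' Degree centrality
#'
#' Raw score counts incident arc endpoints on the multigraph (a self-loop
#' contributes 2). Normalization divides by the maximum raw score; an
#' edgeless graph scores all zero.
#'
#' @param graph A non-empty `pathway_graph`.
#' @return A `centrality_report` with `raw` and `normalized` named vectors.
#' @export
degree_centrality <- function(graph) {
  if (n_nodes(graph) < 1) stop("degree centrality needs >= 1 node",
                               call. = FALSE)
  ids <- node_ids(graph)
  raw <- stats::setNames(numeric(length(ids)), ids)
  for (e in graph$edges) {
    raw[e$source] <- raw[e$source] + 1
    raw[e$target] <- raw[e$target] + 1
  }
  mx <- max(raw)
  normalized <- if (mx > 0) raw / mx else raw
  new_centrality_report("degree", raw, normalized)
}

#' Harmonic closeness centrality
#'
#' Computed on the undirected view of the arc graph:
#' `raw(v) = sum over u != v of 1 / dist(u, v)` with unreachable pairs
#' contributing 0, so disconnected maps (common in pathway data) still get
#' finite scores. Normalization divides by `n - 1`, the score of a node
#' adjacent to everything, where `n` counts nodes participating in the
#' distance graph. Pure containers score 0.
#'
#' @param graph A `pathway_graph` with at least 2 nodes.
#' @return A `centrality_report`.
#' @export
closeness_centrality <- function(graph) {
  if (n_nodes(graph) < 2) stop("closeness centrality needs >= 2 nodes",
                               call. = FALSE)
  ids <- participating_nodes(graph)
  rep <- zero_report(graph, "closeness")
  if (length(ids) < 2) return(rep)
  adj <- undirected_adjacency(graph, ids)
  for (v in ids) {
    d <- flat_bfs(adj, v)
    d <- d[names(d) != v]
    rep$raw[v] <- sum(1 / d)
  }
  rep$normalized[ids] <- rep$raw[ids] / (length(ids) - 1)
  rep
}

flat_bfs <- function(adj, start) {
  dist <- stats::setNames(0L, start)
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    if (is.null(nxt)) break
    frontier <- nxt[!(nxt %in% names(dist))]
    d <- d + 1L
    if (length(frontier)) dist[frontier] <- d
  }
  dist
}

#' Betweenness centrality
#'
#' Brandes' accumulation on the undirected view of the arc graph, endpoints
#' excluded; each unordered pair is counted once. Normalization divides by
#' `(n - 1)(n - 2) / 2`, the number of pairs a node could possibly sit
#' between, with `n` the count of participating nodes.
#'
#' @param graph A `pathway_graph` with at least 3 nodes.
#' @return A `centrality_report`.
#' @export
betweenness_centrality <- function(graph) {
  if (n_nodes(graph) < 3) stop("betweenness centrality needs >= 3 nodes",
                               call. = FALSE)
  ids <- participating_nodes(graph)
  rep <- zero_report(graph, "betweenness")
  n <- length(ids)
  if (n < 3) return(rep)
  adj <- undirected_adjacency(graph, ids)
  bc <- stats::setNames(numeric(n), ids)
  for (s in ids) {
    # single-source shortest-path counts
    sigma <- stats::setNames(numeric(n), ids); sigma[s] <- 1
    dist <- stats::setNames(rep(-1L, n), ids); dist[s] <- 0L
    preds <- stats::setNames(vector("list", n), ids)
    order_visited <- character(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- stats::setNames(numeric(n), ids)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair visited from both endpoints
  rep$raw[ids] <- bc
  rep$normalized[ids] <- bc / ((n - 1) * (n - 2) / 2)
  rep
}

#' PageRank
#'
#' Power iteration on the directed multigraph (parallel arcs count as
#' multiplicity). Dangling nodes redistribute their mass uniformly over the
#' participating nodes. Raw scores sum to 1; normalized scores divide by the
#' maximum.
#'
#' @param graph A non-empty `pathway_graph`.
#' @param damping Damping factor (probability of following an arc).
#' @param tol Convergence threshold on the L1 change per iteration.
#' @param max_iter Iteration cap.
#' @return A `centrality_report`.
#' @export
pagerank <- function(graph, damping = 0.85, tol = 1e-8, max_iter = 100L) {
  if (n_nodes(graph) < 1) stop("pagerank needs >= 1 node", call. = FALSE)
  ids <- participating_nodes(graph)
  rep <- zero_report(graph, "pagerank")
  n <- length(ids)
  if (n == 0) return(rep)
  idx <- stats::setNames(seq_len(n), ids)
  src <- integer(0); dst <- integer(0)
  for (e in graph$edges) {
    if ((e$source %in% ids) && (e$target %in% ids)) {
      src <- c(src, idx[[e$source]])
      dst <- c(dst, idx[[e$target]])
    }
  }
  outdeg <- tabulate(src, nbins = n)
  pr <- rep.int(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- ifelse(outdeg > 0, pr / pmax(outdeg, 1), 0)
    new_pr <- rep.int(0, n)
    if (length(src)) {
      sums <- vapply(split(contrib[src], dst), sum, numeric(1))
      new_pr[as.integer(names(sums))] <- sums
    }
    dangling <- sum(pr[outdeg == 0])
    new_pr <- (1 - damping) / n + damping * (new_pr + dangling / n)
    if (sum(abs(new_pr - pr)) < tol) {
      pr <- new_pr
      break
    }
    pr <- new_pr
  }
  rep$raw[ids] <- pr
  rep$normalized[ids] <- pr / max(pr)
  rep
}

#' Compute a centrality report by name
#'
#' @param graph A `pathway_graph`.
#' @param measure One of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"pagerank"`.
#' @param ... Passed to the specific measure (e.g. `damping` for pagerank).
#' @return A `centrality_report`.
#' @export
centrality <- function(graph, measure, ...) {
  measure <- match.arg(measure, CENTRALITY_MEASURES)
  switch(measure,
         degree = degree_centrality(graph),
         closeness = closeness_centrality(graph),
         betweenness = betweenness_centrality(graph),
         pagerank = pagerank(graph, ...))
}

#' Annotate node labels and highlight thickness with centrality scores
#'
#' Appends the normalized score, rounded to `decimals`, to every node label
#' ("TP53" with score 0.4567 becomes "TP53 (0.46)") and stores the score in
#' each node's `highlight_thickness` attribute, which the renderer maps to
#' highlight stroke width (higher score, thicker highlight).
#'
#' @param graph A `pathway_graph`.
#' @param report A `centrality_report` covering all graph nodes.
#' @param decimals Rounding for the label display.
#' @return The annotated graph.
#' @export
annotate_with_centrality <- function(graph, report, decimals = 2L) {
  stopifnot(inherits(report, "centrality_report"))
  missing <- setdiff(node_ids(graph), names(report$normalized))
  if (length(missing)) {
    stop(sprintf("centrality report lacks node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (id in node_ids(graph)) {
    val <- report$normalized[[id]]
    graph$nodes[[id]]$label <- sprintf(
      "%s (%s)", graph$nodes[[id]]$label,
      formatC(round(val, decimals), format = "f", digits = decimals))
    graph$nodes[[id]]$highlight_thickness <- val
  }
  graph
}
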