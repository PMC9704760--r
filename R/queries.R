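DIRECTIONS <- c("downstream", "upstream", "both")

#' Query options
#'
#' Bundle of tuning knobs shared by the graph-mining queries.
#'
#' @param direction One of `"downstream"` (follow arcs source to target),
#'   `"upstream"` (reverse), or `"both"` (ignore orientation).
#' @param limit_k Maximum path/link length counted in *arcs*; containment
#'   hops are free. `Inf` disables the cap.
#' @param additional_d Shortest-path relaxation for the paths-from-to query:
#'   per source--target pair, paths up to `additional_d` arcs longer than the
#'   pair's shortest distance are admitted.
#' @param max_paths Enumeration guard: path-enumeration queries abort with an
#'   error beyond this many paths (path counts grow exponentially in dense
#'   maps).
#' @return A `query_options` list.
#' @export
query_options <- function(direction = "downstream", limit_k = Inf,
                          additional_d = 0L, max_paths = 10000L) {
  direction <- match.arg(direction, DIRECTIONS)
  stopifnot(length(limit_k) == 1, limit_k >= 0,
            length(additional_d) == 1, additional_d >= 0, max_paths >= 1)
  structure(list(direction = direction, limit_k = limit_k,
                 additional_d = additional_d, max_paths = max_paths),
            class = "query_options")
}

new_query_result <- function(result_nodes = character(0),
                             result_edges = character(0),
                             seed_nodes = character(0),
                             distances = integer(0),
                             paths = list(),
                             roles = NULL) {
  structure(list(result_nodes = unique(result_nodes),
                 result_edges = unique(result_edges),
                 seed_nodes = unique(seed_nodes),
                 distances = distances, paths = paths, roles = roles),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %d seed, %d result nodes, %d edges, %d paths\n",
              length(x$seed_nodes), length(x$result_nodes),
              length(x$result_edges), length(x$paths)))
  invisible(x)
}

check_seeds <- function(graph, ids, what = "source") {
  if (length(ids) == 0) stop(sprintf("%s set is empty", what), call. = FALSE)
  missing <- setdiff(ids, node_ids(graph))
  if (length(missing)) {
    stop(sprintf("unknown %s node(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unique(ids)
}

# Adjacency of the containment-expanded traversal graph. Arcs contribute
# weight-1 steps in the requested direction(s); every parent<->child
# containment link contributes weight-0 steps both ways. Each entry:
# list(w1 = list(to=chr, eid=chr), w0 = chr).
expanded_adjacency <- function(graph, direction) {
  direction <- match.arg(direction, DIRECTIONS)
  ids <- node_ids(graph)
  adj1_to <- stats::setNames(vector("list", length(ids)), ids)
  adj1_eid <- stats::setNames(vector("list", length(ids)), ids)
  adj0 <- stats::setNames(vector("list", length(ids)), ids)
  for (e in graph$edges) {
    if (direction %in% c("downstream", "both")) {
      adj1_to[[e$source]] <- c(adj1_to[[e$source]], e$target)
      adj1_eid[[e$source]] <- c(adj1_eid[[e$source]], e$id)
    }
    if (direction %in% c("upstream", "both")) {
      adj1_to[[e$target]] <- c(adj1_to[[e$target]], e$source)
      adj1_eid[[e$target]] <- c(adj1_eid[[e$target]], e$id)
    }
  }
  for (n in graph$nodes) {
    if (!is.na(n$parent)) {
      adj0[[n$parent]] <- c(adj0[[n$parent]], n$id)
      adj0[[n$id]] <- c(adj0[[n$id]], n$parent)
    }
  }
  list(to = adj1_to, eid = adj1_eid, zero = adj0)
}

#' Compound-aware breadth-first search
#'
#' Layered 0/1 BFS on the containment-expanded graph: reaching a node
#' co-reaches, at the same distance, everything connected to it through
#' containment links (its effective closure, saturated transitively through
#' parents to siblings). Distance counts arcs only.
#'
#' @param graph A `pathway_graph`.
#' @param sources Non-empty character vector of existing node ids.
#' @param direction Traversal direction (see [query_options()]).
#' @param limit_k Maximum distance in arcs; nodes farther away are absent
#'   from the result.
#' @return Named integer vector of distances (sources and their closures at
#'   0).
#' @export
compound_bfs <- function(graph, sources, direction = "downstream",
                         limit_k = Inf) {
  sources <- check_seeds(graph, sources)
  adj <- expanded_adjacency(graph, direction)
  compound_bfs_impl(adj, sources, limit_k)
}

compound_bfs_impl <- function(adj, sources, limit_k) {
  dist <- integer(0)
  frontier <- unique(sources)
  d <- 0L
  visited <- new.env(parent = emptyenv())
  repeat {
    # saturate the frontier under zero-cost containment links
    layer <- character(0)
    while (length(frontier)) {
      fresh <- frontier[!vapply(frontier, exists, logical(1),
                                envir = visited, inherits = FALSE)]
      for (id in fresh) assign(id, TRUE, envir = visited)
      layer <- c(layer, fresh)
      frontier <- unique(unlist(adj$zero[fresh], use.names = FALSE))
      if (is.null(frontier)) frontier <- character(0)
    }
    if (length(layer)) {
      dist[layer] <- d
    }
    if (d >= limit_k || !length(layer)) break
    nxt <- unique(unlist(adj$to[layer], use.names = FALSE))
    if (is.null(nxt)) nxt <- character(0)
    frontier <- nxt[!vapply(nxt, exists, logical(1),
                            envir = visited, inherits = FALSE)]
    if (!length(frontier)) break
    d <- d + 1L
  }
  dist
}

# Arcs whose traversal step was actually taken: the tail (in traversal
# orientation) must be reached at distance < limit_k.
traversed_edges <- function(graph, dist, direction, limit_k) {
  out <- character(0)
  for (e in graph$edges) {
    ok <- FALSE
    if (direction %in% c("downstream", "both")) {
      ds <- dist[e$source]
      if (!is.na(ds) && ds + 1 <= limit_k && !is.na(dist[e$target])) ok <- TRUE
    }
    if (!ok && direction %in% c("upstream", "both")) {
      dt <- dist[e$target]
      if (!is.na(dt) && dt + 1 <= limit_k && !is.na(dist[e$source])) ok <- TRUE
    }
    if (ok) out <- c(out, e$id)
  }
  out
}

#' Neighborhood query
#'
#' Parallel compound BFS from a set of seed nodes; every node discovered
#' within `limit_k` arcs joins the result, together with the arcs traversed
#' to discover it.
#'
#' @inheritParams compound_bfs
#' @return A `query_result`; `distances` holds the BFS distances.
#' @export
neighborhood <- function(graph, sources, direction = "downstream",
                         limit_k = Inf) {
  sources <- check_seeds(graph, sources)
  dist <- compound_bfs(graph, sources, direction, limit_k)
  res_edges <- traversed_edges(graph, dist, direction, limit_k)
  roles <- stats::setNames(rep("result", length(dist)), names(dist))
  roles[sources] <- "seed"
  new_query_result(result_nodes = names(dist), result_edges = res_edges,
                   seed_nodes = sources, distances = dist, roles = roles)
}

#' Common stream query
#'
#' Nodes reachable within `limit_k` arcs, in the chosen direction, from
#' *every* seed: common targets (downstream), common regulators (upstream),
#' or the union of both runs (`"both"`). Arcs and intermediate nodes lying on
#' a qualifying seed-to-common path are reported as connecting links, so the
#' result partitions into disjoint seed / common / link roles.
#'
#' @inheritParams compound_bfs
#' @param sources At least two existing node ids.
#' @return A `query_result`; `roles` maps ids to `"seed"`, `"result"`
#'   (common nodes) or `"link"`; `distances` gives, per common node, the
#'   worst-case (max over seeds) shortest distance.
#' @export
common_stream <- function(graph, sources, direction = "downstream",
                          limit_k = Inf) {
  sources <- check_seeds(graph, sources)
  if (length(sources) < 2) {
    stop("common_stream needs at least 2 sources", call. = FALSE)
  }
  if (direction == "both") {
    a <- common_stream_one(graph, sources, "downstream", limit_k)
    b <- common_stream_one(graph, sources, "upstream", limit_k)
    dists <- a$distances
    for (id in names(b$distances)) {
      dists[id] <- if (is.na(dists[id])) b$distances[id]
                   else min(dists[id], b$distances[id])
    }
    roles <- c(a$roles, b$roles[setdiff(names(b$roles), names(a$roles))])
    # a common node in either run outranks a link role from the other run
    common_ids <- union(names(a$distances), names(b$distances))
    roles[common_ids] <- "result"
    roles[sources] <- "seed"
    return(new_query_result(
      result_nodes = union(a$result_nodes, b$result_nodes),
      result_edges = union(a$result_edges, b$result_edges),
      seed_nodes = sources, distances = dists, roles = roles))
  }
  common_stream_one(graph, sources, direction, limit_k)
}

common_stream_one <- function(graph, sources, direction, limit_k) {
  adj <- expanded_adjacency(graph, direction)
  dmaps <- lapply(sources, function(s) compound_bfs_impl(adj, s, limit_k))
  reached <- lapply(dmaps, names)
  common <- Reduce(intersect, reached)
  common <- setdiff(common, sources)
  if (!length(common)) {
    roles <- stats::setNames(rep("seed", length(sources)), sources)
    return(new_query_result(seed_nodes = sources, roles = roles))
  }
  dists <- vapply(common, function(id) {
    max(vapply(dmaps, function(dm) dm[[id]], integer(1)))
  }, integer(1))
  # distance from any node to the common set, against traversal orientation
  radj <- expanded_adjacency(graph, flip_direction(direction))
  rdist <- compound_bfs_impl(radj, common, limit_k)
  dmin <- dmaps[[1]]
  for (dm in dmaps[-1]) {
    for (id in names(dm)) {
      dmin[id] <- if (is.na(dmin[id])) dm[id] else min(dmin[id], dm[id])
    }
  }
  link_edges <- character(0)
  for (e in graph$edges) {
    tail_id <- if (direction == "downstream") e$source else e$target
    head_id <- if (direction == "downstream") e$target else e$source
    du <- dmin[tail_id]; rv <- rdist[head_id]
    if (!is.na(du) && !is.na(rv) && du + 1 + rv <= limit_k) {
      link_edges <- c(link_edges, e$id)
    }
  }
  on_path <- names(dmin)[!is.na(rdist[names(dmin)]) &
                           dmin + rdist[names(dmin)] <= limit_k]
  link_nodes <- setdiff(on_path, c(sources, common))
  roles <- c(
    stats::setNames(rep("seed", length(sources)), sources),
    stats::setNames(rep("result", length(common)), common),
    stats::setNames(rep("link", length(link_nodes)), link_nodes)
  )
  new_query_result(result_nodes = c(common, link_nodes),
                   result_edges = link_edges,
                   seed_nodes = sources, distances = dists, roles = roles)
}

flip_direction <- function(direction) {
  switch(direction, downstream = "upstream", upstream = "downstream", "both")
}

# Depth-first enumeration of simple paths on the containment-expanded graph.
# Length counts arcs only; zero-cost containment hops may appear inside a
# path. `stop_set`: ids where a path must terminate (recorded, not extended);
# `goal_set`: ids that make a path reportable. `min_len` filters on report.
enumerate_paths <- function(adj, start, goal_set, max_len, stop_set = goal_set,
                            min_len = 1L, max_paths = 10000L) {
  paths <- list()
  edge_sets <- list()
  path_nodes <- start
  path_edges <- character(0)
  in_path <- new.env(parent = emptyenv())
  assign(start, TRUE, envir = in_path)

  recurse <- function(cur, len) {
    if (length(paths) >= max_paths) {
      stop(sprintf("path enumeration exceeded %d paths; tighten k or d",
                   max_paths), call. = FALSE)
    }
    if (cur %in% goal_set && cur != start && len >= min_len) {
      paths[[length(paths) + 1L]] <<- path_nodes
      edge_sets[[length(edge_sets) + 1L]] <<- path_edges
    }
    if (cur %in% stop_set && cur != start) return(invisible())
    # zero-cost containment hops
    for (nb in adj$zero[[cur]]) {
      if (!exists(nb, envir = in_path, inherits = FALSE)) {
        assign(nb, TRUE, envir = in_path)
        path_nodes <<- c(path_nodes, nb)
        recurse(nb, len)
        path_nodes <<- path_nodes[-length(path_nodes)]
        rm(list = nb, envir = in_path)
      }
    }
    if (len >= max_len) return(invisible())
    tos <- adj$to[[cur]]
    eids <- adj$eid[[cur]]
    for (i in seq_along(tos)) {
      nb <- tos[[i]]
      if (!exists(nb, envir = in_path, inherits = FALSE)) {
        assign(nb, TRUE, envir = in_path)
        path_nodes <<- c(path_nodes, nb)
        path_edges <<- c(path_edges, eids[[i]])
        recurse(nb, len + 1L)
        path_nodes <<- path_nodes[-length(path_nodes)]
        path_edges <<- path_edges[-length(path_edges)]
        rm(list = nb, envir = in_path)
      }
    }
    invisible()
  }
  recurse(start, 0L)
  list(paths = paths, edge_sets = edge_sets)
}

#' Paths-between query
#'
#' Finds the "missing links" among a set of nodes of interest: all simple
#' directed paths of at most `limit_k` arcs that start and end at two
#' distinct seeds and pass through no other seed. The union of these paths,
#' together with the seeds themselves, forms a maximal sub-pathway connecting
#' the set.
#'
#' @param graph A `pathway_graph`.
#' @param seeds At least two existing node ids.
#' @param limit_k Maximum link length in arcs (`>= 1`).
#' @param direction Traversal direction; default follows arc orientation.
#' @param max_paths Enumeration guard (error beyond this many paths).
#' @return A `query_result` with the enumerated `paths`.
#' @export
paths_between <- function(graph, seeds, limit_k, direction = "downstream",
                          max_paths = 10000L) {
  seeds <- check_seeds(graph, seeds, "seed")
  if (length(seeds) < 2) stop("paths_between needs at least 2 seeds",
                              call. = FALSE)
  stopifnot(limit_k >= 1)
  adj <- expanded_adjacency(graph, direction)
  all_paths <- list(); all_edges <- character(0); nodes <- seeds
  for (s in seeds) {
    enum <- enumerate_paths(adj, s, goal_set = seeds, max_len = limit_k,
                            stop_set = seeds,
                            max_paths = max_paths - length(all_paths))
    all_paths <- c(all_paths, enum$paths)
    all_edges <- c(all_edges, unlist(enum$edge_sets, use.names = FALSE))
    nodes <- c(nodes, unlist(enum$paths, use.names = FALSE))
  }
  roles <- stats::setNames(rep("link", length(unique(nodes))), unique(nodes))
  roles[seeds] <- "seed"
  new_query_result(result_nodes = nodes, result_edges = all_edges,
                   seed_nodes = seeds, paths = all_paths, roles = roles)
}

#' Paths-from-to query
#'
#' All shortest -- or, with `additional_d > 0`, near-shortest -- simple
#' direction-respecting paths from a source set to a target set. For each
#' ordered pair (s, t), paths of length L(s,t) up to
#' `min(L(s,t) + additional_d, limit_k)` arcs are returned, where L(s,t) is
#' the compound shortest-path distance. With shortest distance 3 and
#' `additional_d = 2`, paths of lengths 3, 4 and 5 qualify.
#'
#' @param graph A `pathway_graph`.
#' @param sources,targets Non-empty character vectors of existing node ids
#'   (need not be disjoint; identical pairs are skipped).
#' @param limit_k Cap on admissible path length in arcs.
#' @param additional_d Relaxation beyond the per-pair shortest distance.
#' @param direction Traversal direction.
#' @param max_paths Enumeration guard.
#' @return A `query_result` with the enumerated `paths`; `distances` holds
#'   compound BFS distances from the source set.
#' @export
paths_from_to <- function(graph, sources, targets, limit_k = Inf,
                          additional_d = 0L, direction = "downstream",
                          max_paths = 10000L) {
  sources <- check_seeds(graph, sources, "source")
  targets <- check_seeds(graph, targets, "target")
  adj <- expanded_adjacency(graph, direction)
  radj <- expanded_adjacency(graph, flip_direction(direction))
  all_paths <- list(); all_edges <- character(0)
  nodes <- character(0)
  for (s in sources) {
    dmap <- compound_bfs_impl(adj, s, Inf)
    for (t in targets) {
      if (s == t) next
      L <- dmap[t]
      if (is.na(L)) next
      max_len <- min(L + additional_d, limit_k)
      if (max_len < L) next
      enum <- enumerate_paths(adj, s, goal_set = t, max_len = max_len,
                              stop_set = character(0), min_len = L,
                              max_paths = max_paths - length(all_paths))
      # keep only paths actually ending at t (enumerate reports on arrival)
      all_paths <- c(all_paths, enum$paths)
      all_edges <- c(all_edges, unlist(enum$edge_sets, use.names = FALSE))
      nodes <- c(nodes, unlist(enum$paths, use.names = FALSE))
    }
  }
  dist_all <- compound_bfs(graph, sources, direction, Inf)
  nodes <- unique(c(nodes, sources, targets))
  roles <- stats::setNames(rep("link", length(nodes)), nodes)
  roles[targets] <- "result"
  roles[sources] <- "seed"
  new_query_result(result_nodes = nodes, result_edges = all_edges,
                   seed_nodes = union(sources, targets),
                   distances = dist_all[names(dist_all) %in% nodes],
                   paths = all_paths, roles = roles)
}

#' Single shortest path
#'
#' One shortest compound path from `source` to `target`; among equally short
#' paths the lexicographically smallest node-id sequence is returned.
#' Containment hops are free and may appear inside the path.
#'
#' @param graph A `pathway_graph`.
#' @param source,target Distinct existing node ids.
#' @param direction Traversal direction.
#' @return A `query_result` whose `paths` holds zero (unreachable) or one
#'   path.
#' @export
shortest_path <- function(graph, source, target, direction = "downstream") {
  check_seeds(graph, source, "source")
  check_seeds(graph, target, "target")
  if (source == target) stop("source and target must differ", call. = FALSE)
  adj <- expanded_adjacency(graph, direction)
  radj <- expanded_adjacency(graph, flip_direction(direction))
  dist_to <- compound_bfs_impl(radj, target, Inf)
  if (is.na(dist_to[source])) {
    return(new_query_result(seed_nodes = c(source, target)))
  }
  total <- dist_to[[source]]
  path_nodes <- source
  path_edges <- character(0)
  in_path <- new.env(parent = emptyenv())
  assign(source, TRUE, envir = in_path)
  found <- NULL; found_edges <- NULL

  dfs <- function(cur, used) {
    if (!is.null(found)) return(invisible())
    if (cur == target) {
      found <<- path_nodes
      found_edges <<- path_edges
      return(invisible())
    }
    # candidate next steps that stay on some shortest path, smallest id first
    cand <- list()
    for (nb in adj$zero[[cur]]) {
      r <- dist_to[nb]
      if (!is.na(r) && used + r == total &&
          !exists(nb, envir = in_path, inherits = FALSE)) {
        cand[[length(cand) + 1L]] <- list(to = nb, w = 0L, eid = NA_character_)
      }
    }
    tos <- adj$to[[cur]]; eids <- adj$eid[[cur]]
    if (used < total) {
      for (i in seq_along(tos)) {
        nb <- tos[[i]]
        r <- dist_to[nb]
        if (!is.na(r) && used + 1L + r == total &&
            !exists(nb, envir = in_path, inherits = FALSE)) {
          cand[[length(cand) + 1L]] <- list(to = nb, w = 1L, eid = eids[[i]])
        }
      }
    }
    if (!length(cand)) return(invisible())
    ord <- order(vapply(cand, `[[`, character(1), "to"), method = "radix")
    for (i in ord) {
      st <- cand[[i]]
      assign(st$to, TRUE, envir = in_path)
      path_nodes <<- c(path_nodes, st$to)
      if (!is.na(st$eid)) path_edges <<- c(path_edges, st$eid)
      dfs(st$to, used + st$w)
      if (!is.null(found)) return(invisible())
      path_nodes <<- path_nodes[-length(path_nodes)]
      if (!is.na(st$eid)) path_edges <<- path_edges[-length(path_edges)]
      rm(list = st$to, envir = in_path)
    }
    invisible()
  }
  dfs(source, 0L)
  if (is.null(found)) {
    return(new_query_result(seed_nodes = c(source, target)))
  }
  roles <- stats::setNames(rep("link", length(found)), found)
  roles[c(source, target)] <- "seed"
  new_query_result(result_nodes = found, result_edges = found_edges,
                   seed_nodes = c(source, target),
                   paths = list(found), roles = roles)
}
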