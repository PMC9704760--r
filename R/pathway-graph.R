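# Closed vocabularies (subset of SBGN PD glyph/arc classes).
NODE_CLASSES <- c(
  "macromolecule", "simple_chemical", "nucleic_acid_feature",
  "unspecified_entity", "complex", "compartment", "process",
  "association", "dissociation", "phenotype", "source_sink", "generic"
)
COMPOUND_CLASSES <- c("compartment", "complex")
EDGE_CLASSES <- c(
  "consumption", "production", "catalysis", "stimulation",
  "inhibition", "modulation", "generic"
)

#' Create an empty pathway graph
#'
#' A pathway graph is a directed multigraph (parallel arcs and self-loops
#' allowed) over typed nodes, together with a containment forest: compartment
#' and complex nodes may contain other nodes. Containment is *not* an edge --
#' arc-based algorithms see only the explicit arcs, while compound-aware
#' traversals treat containment as free (zero-cost) connectivity.
#'
#' @return An object of class `pathway_graph` with zero nodes and edges.
#' @seealso [add_node()], [add_edge()], [descendants()], [effective_closure()]
#' @export
#' @examples
#' g <- pathway_graph()
#' g <- add_node(g, "C", class = "compartment")
#' g <- add_node(g, "TP53", class = "macromolecule", parent = "C")
pathway_graph <- function() {
  structure(
    list(nodes = list(), edges = list(), children = list()),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  nc <- length(x$nodes)
  ec <- length(x$edges)
  comp <- sum(vapply(x$nodes, function(n) n$class %in% COMPOUND_CLASSES, logical(1)))
  cat(sprintf("<pathway_graph> %d nodes (%d compound), %d edges\n", nc, comp, ec))
  invisible(x)
}

#' Node class vocabulary
#'
#' @return Character vector of the closed node-class enumeration. Compartment
#'   and complex are the only compound-capable (container) classes.
#' @export
node_classes <- function() NODE_CLASSES

#' Edge class vocabulary
#'
#' @return Character vector of the closed arc-class enumeration.
#' @export
edge_classes <- function() EDGE_CLASSES

is_compound_class <- function(class) class %in% COMPOUND_CLASSES

check_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  }
  x
}

#' Add a node to a pathway graph
#'
#' @param graph A `pathway_graph`.
#' @param id Unique node id.
#' @param label Display label; defaults to the id.
#' @param class One of [node_classes()].
#' @param parent Optional id of an existing compound-capable node
#'   (compartment or complex).
#' @param geometry Optional list with fields `x`, `y` (center, px, y grows
#'   downward), `w`, `h` (px, positive).
#' @return The updated graph.
#' @export
add_node <- function(graph, id, label = id, class = "generic",
                     parent = NULL, geometry = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  check_scalar_chr(id, "node id")
  if (!is.null(graph$nodes[[id]])) {
    stop(sprintf("duplicate node id '%s'", id), call. = FALSE)
  }
  class <- match.arg(class, NODE_CLASSES)
  if (!is.null(parent)) {
    check_scalar_chr(parent, "parent id")
    pn <- graph$nodes[[parent]]
    if (is.null(pn)) {
      stop(sprintf("parent '%s' of node '%s' does not exist", parent, id),
           call. = FALSE)
    }
    if (!is_compound_class(pn$class)) {
      stop(sprintf("parent '%s' has class '%s', which cannot contain nodes",
                   parent, pn$class), call. = FALSE)
    }
  }
  geometry <- validate_geometry(geometry, id)
  graph$nodes[[id]] <- list(
    id = id, label = label, class = class,
    parent = if (is.null(parent)) NA_character_ else parent,
    geometry = geometry
  )
  if (!is.null(parent)) {
    graph$children[[parent]] <- c(graph$children[[parent]], id)
  }
  graph
}

validate_geometry <- function(geometry, id) {
  if (is.null(geometry)) return(NULL)
  need <- c("x", "y", "w", "h")
  if (!all(need %in% names(geometry))) {
    stop(sprintf("geometry of '%s' must have x, y, w, h", id), call. = FALSE)
  }
  g <- lapply(geometry[need], as.numeric)
  if (!all(vapply(g, function(v) length(v) == 1 && is.finite(v), logical(1)))) {
    stop(sprintf("geometry of '%s' must be finite scalars", id), call. = FALSE)
  }
  if (g$w <= 0 || g$h <= 0) {
    stop(sprintf("geometry of '%s' must have positive width and height", id),
         call. = FALSE)
  }
  g
}

#' Add a directed edge (arc) to a pathway graph
#'
#' Parallel edges and self-loops are permitted; containment is never an edge.
#'
#' @param graph A `pathway_graph`.
#' @param id Unique edge id.
#' @param source,target Existing node ids.
#' @param class One of [edge_classes()].
#' @return The updated graph.
#' @export
add_edge <- function(graph, id, source, target, class = "generic") {
  stopifnot(inherits(graph, "pathway_graph"))
  check_scalar_chr(id, "edge id")
  if (!is.null(graph$edges[[id]])) {
    stop(sprintf("duplicate edge id '%s'", id), call. = FALSE)
  }
  class <- match.arg(class, EDGE_CLASSES)
  for (endp in c(source, target)) {
    if (is.null(graph$nodes[[endp]])) {
      stop(sprintf("edge '%s' references missing node '%s'", id, endp),
           call. = FALSE)
    }
  }
  graph$edges[[id]] <- list(id = id, source = source, target = target,
                            class = class)
  graph
}

#' Remove a node
#'
#' Fails if the node still has children or incident edges, so removal is
#' always the exact inverse of the corresponding [add_node()].
#' @param graph A `pathway_graph`.
#' @param id Node id.
#' @return The updated graph.
#' @export
remove_node <- function(graph, id) {
  n <- get_node(graph, id)
  if (length(graph$children[[id]]) > 0) {
    stop(sprintf("node '%s' still contains children", id), call. = FALSE)
  }
  incident <- vapply(graph$edges, function(e) e$source == id || e$target == id,
                     logical(1))
  if (any(incident)) {
    stop(sprintf("node '%s' still has incident edges", id), call. = FALSE)
  }
  if (!is.na(n$parent)) {
    sib <- graph$children[[n$parent]]
    sib <- sib[sib != id]
    if (length(sib)) graph$children[[n$parent]] <- sib
    else graph$children[[n$parent]] <- NULL
  }
  graph$nodes[[id]] <- NULL
  graph
}

#' Remove an edge
#' @param graph A `pathway_graph`.
#' @param id Edge id.
#' @return The updated graph.
#' @export
remove_edge <- function(graph, id) {
  if (is.null(graph$edges[[id]])) {
    stop(sprintf("unknown edge '%s'", id), call. = FALSE)
  }
  graph$edges[[id]] <- NULL
  graph
}

#' @rdname pathway_graph_accessors
#' @export
node_ids <- function(graph) names(graph$nodes)

#' @rdname pathway_graph_accessors
#' @export
edge_ids <- function(graph) names(graph$edges)

#' Pathway graph accessors
#'
#' @param graph A `pathway_graph`.
#' @param id A node or edge id.
#' @return `node_ids()`/`edge_ids()` return character vectors; `get_node()`/
#'   `get_edge()` return the stored record (error on unknown id);
#'   `n_nodes()`/`n_edges()` return counts.
#' @name pathway_graph_accessors
#' @export
get_node <- function(graph, id) {
  n <- graph$nodes[[id]]
  if (is.null(n)) stop(sprintf("unknown node '%s'", id), call. = FALSE)
  n
}

#' @rdname pathway_graph_accessors
#' @export
get_edge <- function(graph, id) {
  e <- graph$edges[[id]]
  if (is.null(e)) stop(sprintf("unknown edge '%s'", id), call. = FALSE)
  e
}

#' @rdname pathway_graph_accessors
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname pathway_graph_accessors
#' @export
n_edges <- function(graph) length(graph$edges)

#' Containment descendants of a node
#'
#' All nodes whose ancestor chain contains `id`, in depth-first order
#' (children in insertion order), excluding `id` itself.
#'
#' @param graph A `pathway_graph`.
#' @param id Node id.
#' @return Character vector of node ids (possibly empty).
#' @export
descendants <- function(graph, id) {
  get_node(graph, id)
  out <- character(0)
  stack <- rev(graph$children[[id]])
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    kids <- graph$children[[cur]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

#' Containment ancestors of a node
#'
#' Parent chain of `id`, nearest first, root last.
#'
#' @inheritParams descendants
#' @return Character vector of node ids (possibly empty).
#' @export
ancestors <- function(graph, id) {
  n <- get_node(graph, id)
  out <- character(0)
  p <- n$parent
  while (!is.na(p)) {
    out <- c(out, p)
    p <- graph$nodes[[p]]$parent
  }
  out
}

#' Effective closure of a node for compound traversal
#'
#' The set of nodes considered co-reached, at zero cost, when `id` is reached
#' during a compound-aware traversal: the node itself, its containment
#' ancestors, and its containment descendants. Siblings are *not* part of the
#' closure; a traversal reaches them transitively through the parent in its
#' next zero-cost expansion.
#'
#' @inheritParams descendants
#' @return Character vector of node ids including `id`.
#' @export
effective_closure <- function(graph, id) {
  unique(c(id, ancestors(graph, id), descendants(graph, id)))
}

#' Set or replace a node's geometry
#'
#' @param graph A `pathway_graph`.
#' @param id Node id.
#' @param x,y Center coordinates in px (y grows downward).
#' @param w,h Width and height in px, positive.
#' @return The updated graph.
#' @export
set_geometry <- function(graph, id, x, y, w, h) {
  get_node(graph, id)
  graph$nodes[[id]]$geometry <-
    validate_geometry(list(x = x, y = y, w = w, h = h), id)
  graph
}

#' Extract the geometry map of a graph
#'
#' @param graph A `pathway_graph`.
#' @return Named list `id -> list(x, y, w, h)`; nodes without geometry are
#'   omitted.
#' @export
geometry_map <- function(graph) {
  out <- lapply(graph$nodes, `[[`, "geometry")
  out[!vapply(out, is.null, logical(1))]
}

#' Apply a geometry map to a graph
#'
#' @param graph A `pathway_graph`.
#' @param geometry Named list `id -> list(x, y, w, h)` (as produced by
#'   [layout_pathway()]).
#' @return The updated graph.
#' @export
apply_geometry <- function(graph, geometry) {
  for (id in names(geometry)) {
    gm <- geometry[[id]]
    graph <- set_geometry(graph, id, gm$x, gm$y, gm$w, gm$h)
  }
  graph
}

#' Validate all pathway-graph invariants
#'
#' Checks endpoint existence, id uniqueness, parent links forming a forest,
#' parents being compound-capable, and geometry sanity. Intended for use
#' after bulk construction (e.g. by the format readers).
#'
#' @param graph A `pathway_graph`.
#' @return `graph`, invisibly; errors on the first violated invariant.
#' @export
validate_pathway_graph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- names(graph$nodes)
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(names(graph$edges))) stop("duplicate edge ids", call. = FALSE)
  for (n in graph$nodes) {
    if (!n$class %in% NODE_CLASSES) {
      stop(sprintf("node '%s' has unknown class '%s'", n$id, n$class),
           call. = FALSE)
    }
    if (!is.na(n$parent)) {
      p <- graph$nodes[[n$parent]]
      if (is.null(p)) stop(sprintf("node '%s' has missing parent", n$id),
                           call. = FALSE)
      if (!is_compound_class(p$class)) {
        stop(sprintf("parent of '%s' is not compound-capable", n$id),
             call. = FALSE)
      }
      # forest check: walk up, fail on revisit
      seen <- n$id
      cur <- n$parent
      while (!is.na(cur)) {
        if (cur %in% seen) stop("containment cycle detected", call. = FALSE)
        seen <- c(seen, cur)
        cur <- graph$nodes[[cur]]$parent
      }
    }
    if (!is.null(n$geometry)) validate_geometry(n$geometry, n$id)
  }
  for (e in graph$edges) {
    if (is.null(graph$nodes[[e$source]]) || is.null(graph$nodes[[e$target]])) {
      stop(sprintf("edge '%s' has a dangling endpoint", e$id), call. = FALSE)
    }
    if (!e$class %in% EDGE_CLASSES) {
      stop(sprintf("edge '%s' has unknown class '%s'", e$id, e$class),
           call. = FALSE)
    }
  }
  invisible(graph)
}

# Preorder over the containment forest: every parent precedes its
# descendants; roots and siblings keep insertion order. Used by the renderer
# (z-order) and the writers.
containment_preorder <- function(graph) {
  ids <- names(graph$nodes)
  if (!length(ids)) return(character(0))
  roots <- ids[vapply(graph$nodes, function(n) is.na(n$parent), logical(1))]
  out <- character(0)
  stack <- rev(roots)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    kids <- graph$children[[cur]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}
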