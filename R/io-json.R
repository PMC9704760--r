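# --- shared reader plumbing -------------------------------------------------

new_parse_report <- function(graph, warnings, source_format) {
  structure(list(graph = graph, warnings = warnings,
                 source_format = source_format),
            class = "parse_report")
}

#' @export
print.parse_report <- function(x, ...) {
  cat(sprintf("<parse_report> [%s] %d nodes, %d edges, %d warning(s)\n",
              x$source_format, n_nodes(x$graph), n_edges(x$graph),
              length(x$warnings)))
  if (length(x$warnings)) cat(paste0("  ! ", x$warnings, "\n"), sep = "")
  invisible(x)
}

# Insert node records parent-first (parents may appear later in the source
# document than their members), then the edges. Errors carry the offending id.
build_graph_from_records <- function(node_records, edge_records) {
  g <- pathway_graph()
  pending <- node_records
  repeat {
    progressed <- FALSE
    still <- list()
    for (rec in pending) {
      if (is.null(rec$parent) || !is.null(g$nodes[[rec$parent]])) {
        g <- add_node(g, rec$id, label = rec$label, class = rec$class,
                      parent = rec$parent, geometry = rec$geometry)
        progressed <- TRUE
      } else {
        still[[length(still) + 1L]] <- rec
      }
    }
    pending <- still
    if (!length(pending)) break
    if (!progressed) {
      bad <- vapply(pending, `[[`, character(1), "id")
      stop(sprintf("unresolvable parent reference(s) for node(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  for (rec in edge_records) {
    g <- add_edge(g, rec$id, rec$source, rec$target, class = rec$class)
  }
  g
}

# Tolerant class normalization shared by all readers: SBGN-style names with
# spaces are accepted; anything unrecognized degrades to "generic" and is
# reported via the returned attribute.
normalize_node_class <- function(class) {
  if (is.null(class) || !nzchar(class)) return("generic")
  key <- gsub("[ -]+", "_", tolower(trimws(class)))
  if (key == "source_and_sink" || key == "empty_set") key <- "source_sink"
  if (key %in% NODE_CLASSES) key else NA_character_
}

normalize_edge_class <- function(class) {
  if (is.null(class) || !nzchar(class)) return("generic")
  key <- gsub("[ -]+", "_", tolower(trimws(class)))
  if (key == "necessary_stimulation") key <- "stimulation"
  if (key %in% EDGE_CLASSES) key else NA_character_
}

# --- elements-JSON ----------------------------------------------------------

#' Read a pathway graph from elements JSON
#'
#' The elements dialect: a JSON list (or an object with `nodes` and `edges`
#' lists) of elements. A node element is
#' `{"data": {"id", "label"?, "class"?, "parent"?, "width"?, "height"?},
#' "position"?: {"x", "y"}}`; an edge element is
#' `{"data": {"id"?, "source", "target", "class"?}}`. Positions are node
#' centers in px, y growing downward. Absent edge ids are generated
#' deterministically as `"e0"`, `"e1"`, ... in input order.
#'
#' @param text JSON text.
#' @return A `parse_report` (graph + warnings + source format).
#' @export
read_json_elements <- function(text) {
  parsed <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.list(parsed) && !is.null(names(parsed)) &&
      any(c("nodes", "edges") %in% names(parsed))) {
    elements <- c(parsed$nodes, parsed$edges)
  } else {
    elements <- parsed
  }
  warnings <- character(0)
  node_records <- list(); edge_records <- list()
  auto_i <- 0L
  taken_ids <- unlist(lapply(elements, function(el) el$data$id))
  for (el in elements) {
    d <- el$data
    if (is.null(d)) stop("element without a data block", call. = FALSE)
    is_edge <- !is.null(d$source) || !is.null(d$target)
    if (is_edge) {
      if (is.null(d$source) || is.null(d$target)) {
        stop("edge element with missing endpoint", call. = FALSE)
      }
      id <- d$id
      if (is.null(id)) {
        repeat {
          id <- sprintf("e%d", auto_i)
          auto_i <- auto_i + 1L
          if (!id %in% taken_ids) break
        }
        taken_ids <- c(taken_ids, id)
      }
      cls <- normalize_edge_class(d$class)
      if (is.na(cls)) {
        warnings <- c(warnings, sprintf(
          "unknown edge class '%s' on '%s' mapped to generic", d$class, id))
        cls <- "generic"
      }
      edge_records[[length(edge_records) + 1L]] <-
        list(id = id, source = d$source, target = d$target, class = cls)
    } else {
      if (is.null(d$id)) stop("node element without id", call. = FALSE)
      cls <- normalize_node_class(d$class)
      if (is.na(cls)) {
        warnings <- c(warnings, sprintf(
          "unknown node class '%s' on '%s' mapped to generic", d$class, d$id))
        cls <- "generic"
      }
      geometry <- NULL
      if (!is.null(el$position)) {
        geometry <- list(
          x = el$position$x, y = el$position$y,
          w = if (is.null(d$width)) 40 else d$width,
          h = if (is.null(d$height)) 40 else d$height
        )
      }
      node_records[[length(node_records) + 1L]] <- list(
        id = d$id, label = if (is.null(d$label)) d$id else d$label,
        class = cls, parent = d$parent, geometry = geometry)
    }
  }
  g <- build_graph_from_records(node_records, edge_records)
  new_parse_report(validate_pathway_graph(g), warnings, "json")
}

#' Write a pathway graph as elements JSON
#'
#' Inverse of [read_json_elements()]: the emitted text re-parses to a graph
#' with identical ids, labels, classes, parents and positions. Nodes are
#' written in containment preorder (parents before members), then edges.
#'
#' @param graph A `pathway_graph`.
#' @return JSON text.
#' @export
write_elements_json <- function(graph) {
  elements <- list()
  for (id in containment_preorder(graph)) {
    n <- graph$nodes[[id]]
    d <- list(id = n$id, label = n$label, class = n$class)
    if (!is.na(n$parent)) d$parent <- n$parent
    el <- list(data = d)
    if (!is.null(n$geometry)) {
      el$data$width <- n$geometry$w
      el$data$height <- n$geometry$h
      el$position <- list(x = n$geometry$x, y = n$geometry$y)
    }
    elements[[length(elements) + 1L]] <- el
  }
  for (e in graph$edges) {
    elements[[length(elements) + 1L]] <- list(
      data = list(id = e$id, source = e$source, target = e$target,
                  class = e$class))
  }
  as.character(jsonlite::toJSON(elements, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' Write per-node layout information as JSON
#'
#' @param graph A `pathway_graph` in which every node has geometry.
#' @return JSON text: an object mapping node id to `{x, y, w, h}` (centers,
#'   px), keys sorted for stable serialization.
#' @export
write_layout_json <- function(graph) {
  gm <- geometry_map(graph)
  missing <- setdiff(node_ids(graph), names(gm))
  if (length(missing)) {
    stop(sprintf("node(s) without geometry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!length(gm)) return("{}")
  gm <- gm[order(names(gm), method = "radix")]
  as.character(jsonlite::toJSON(gm, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}
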