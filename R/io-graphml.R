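GRAPHML_NODE_KEYS <- c("label", "class", "x", "y", "w", "h")

#' Read a pathway graph from GraphML
#'
#' Nested `<graph>` elements inside `<node>` elements denote compound nodes;
#' nesting becomes containment links. Node data keys `label`, `class`, `x`,
#' `y`, `w`, `h` and the edge data key `class` are honored when declared
#' (matched by `attr.name`). Missing classes default to `generic`; `x`/`y`
#' are node centers and default sizes are 40x40 px.
#'
#' @param text GraphML document text.
#' @param key_map Optional named character vector remapping attribute names,
#'   e.g. `c(label = "name")` to read labels from an attribute declared as
#'   `name`.
#' @return A `parse_report`.
#' @export
read_graphml <- function(text, key_map = NULL) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "graphml") {
    stop("not a GraphML document (root is not <graphml>)", call. = FALSE)
  }
  wanted <- stats::setNames(GRAPHML_NODE_KEYS, GRAPHML_NODE_KEYS)
  if (!is.null(key_map)) wanted[names(key_map)] <- key_map
  # key id -> canonical attribute name
  key_lookup <- character(0)
  for (k in xml2::xml_find_all(doc, "./key")) {
    kid <- xml2::xml_attr(k, "id")
    aname <- xml2::xml_attr(k, "attr.name")
    if (is.na(aname)) aname <- kid
    hit <- names(wanted)[wanted == aname]
    if (length(hit)) key_lookup[kid] <- hit[[1]]
    if (aname == "class") key_lookup[kid] <- "class"
  }

  warnings <- character(0)
  node_records <- list()
  edge_records <- list()
  declared <- character(0)
  auto_i <- 0L

  read_data <- function(el) {
    out <- list()
    for (d in xml2::xml_find_all(el, "./data")) {
      kid <- xml2::xml_attr(d, "key")
      if (!is.na(kid) && kid %in% names(key_lookup)) {
        out[[key_lookup[[kid]]]] <- xml2::xml_text(d)
      }
    }
    out
  }

  walk_graph <- function(graph_el, parent_id) {
    for (nd in xml2::xml_find_all(graph_el, "./node")) {
      id <- xml2::xml_attr(nd, "id")
      if (is.na(id)) stop("GraphML node without id", call. = FALSE)
      declared <<- c(declared, id)
      dat <- read_data(nd)
      cls <- normalize_node_class(dat$class)
      if (is.na(cls)) {
        warnings <<- c(warnings, sprintf(
          "unknown node class '%s' on '%s' mapped to generic", dat$class, id))
        cls <- "generic"
      }
      sub <- xml2::xml_find_first(nd, "./graph")
      if (!inherits(sub, "xml_missing") && !is_compound_class(cls)) {
        # a nested graph forces a compound-capable class
        if (!is.null(dat$class)) {
          warnings <<- c(warnings, sprintf(
            "node '%s' contains a nested graph; class coerced to compartment",
            id))
        }
        cls <- "compartment"
      }
      geometry <- NULL
      if (!is.null(dat$x) && !is.null(dat$y)) {
        geometry <- list(
          x = as.numeric(dat$x), y = as.numeric(dat$y),
          w = if (is.null(dat$w)) 40 else as.numeric(dat$w),
          h = if (is.null(dat$h)) 40 else as.numeric(dat$h))
      }
      node_records[[length(node_records) + 1L]] <<- list(
        id = id, label = if (is.null(dat$label)) id else dat$label,
        class = cls, parent = parent_id, geometry = geometry)
      if (!inherits(sub, "xml_missing")) walk_graph(sub, id)
    }
    for (ed in xml2::xml_find_all(graph_el, "./edge")) {
      id <- xml2::xml_attr(ed, "id")
      if (is.na(id)) {
        id <- sprintf("e%d", auto_i)
        auto_i <<- auto_i + 1L
      }
      dat <- read_data(ed)
      cls <- normalize_edge_class(dat$class)
      if (is.na(cls)) {
        warnings <<- c(warnings, sprintf(
          "unknown edge class '%s' on '%s' mapped to generic", dat$class, id))
        cls <- "generic"
      }
      src <- xml2::xml_attr(ed, "source")
      tgt <- xml2::xml_attr(ed, "target")
      edge_records[[length(edge_records) + 1L]] <<- list(
        id = id, source = src, target = tgt, class = cls)
    }
    invisible()
  }
  root_graph <- xml2::xml_find_first(doc, "./graph")
  if (!inherits(root_graph, "xml_missing")) walk_graph(root_graph, NULL)

  for (rec in edge_records) {
    if (!(rec$source %in% declared) || !(rec$target %in% declared)) {
      stop(sprintf("edge '%s' references undeclared node", rec$id),
           call. = FALSE)
    }
  }
  g <- build_graph_from_records(node_records, edge_records)
  new_parse_report(validate_pathway_graph(g), warnings, "graphml")
}

#' Write a pathway graph as GraphML
#'
#' Containment is written as nested `<graph>` elements; labels, classes and
#' center geometry go into declared data keys. All edges live in the root
#' graph (GraphML scoping permits referencing nested nodes there).
#'
#' @param graph A `pathway_graph`.
#' @return GraphML text.
#' @export
write_graphml <- function(graph) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    c("d_label", "node", "label", "string"),
    c("d_class", "node", "class", "string"),
    c("d_x", "node", "x", "double"),
    c("d_y", "node", "y", "double"),
    c("d_w", "node", "w", "double"),
    c("d_h", "node", "h", "double"),
    c("d_eclass", "edge", "class", "string")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  }
  root <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")

  emit_node <- function(parent_xml, id) {
    n <- graph$nodes[[id]]
    nd <- xml2::xml_add_child(parent_xml, "node", id = id)
    add_data <- function(key, value) {
      d <- xml2::xml_add_child(nd, "data", key = key)
      xml2::xml_text(d) <- as.character(value)
    }
    add_data("d_label", n$label)
    add_data("d_class", n$class)
    if (!is.null(n$geometry)) {
      add_data("d_x", n$geometry$x); add_data("d_y", n$geometry$y)
      add_data("d_w", n$geometry$w); add_data("d_h", n$geometry$h)
    }
    kids <- graph$children[[id]]
    if (length(kids)) {
      sub <- xml2::xml_add_child(nd, "graph", id = paste0(id, ":g"),
                                 edgedefault = "directed")
      for (kid in kids) emit_node(sub, kid)
    }
  }
  roots <- node_ids(graph)[vapply(graph$nodes, function(n) is.na(n$parent),
                                  logical(1))]
  for (r in roots) emit_node(root, r)
  for (e in graph$edges) {
    ed <- xml2::xml_add_child(root, "edge", id = e$id, source = e$source,
                              target = e$target)
    d <- xml2::xml_add_child(ed, "data", key = "d_eclass")
    xml2::xml_text(d) <- e$class
  }
  as.character(doc)
}
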