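SBGN_SKIP_GLYPHS <- c("state variable", "unit of information", "port",
                      "annotation", "cardinality")

#' Read a pathway graph from SBGNML (process description)
#'
#' Glyphs become nodes (class mapped from the SBGN glyph class; unknown
#' classes degrade to `generic` with a warning), glyph nesting and
#' `compartmentRef` become containment links, and arcs become edges. Arcs
#' that reference ports are resolved to the port-owning glyph. Bounding boxes
#' (top-left corner per the standard) are converted to center coordinates.
#' State variables and units of information are absorbed (skipped), not
#' modeled.
#'
#' @param text SBGNML document text (0.2 or 0.3, map language
#'   "process description").
#' @return A `parse_report`.
#' @export
read_sbgnml <- function(text) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbgn") {
    stop("not an SBGNML document (root is not <sbgn>)", call. = FALSE)
  }
  map <- xml2::xml_find_first(doc, ".//map")
  if (inherits(map, "xml_missing")) {
    stop("SBGNML document has no <map>", call. = FALSE)
  }
  lang <- xml2::xml_attr(map, "language")
  warnings <- character(0)
  if (is.na(lang)) {
    warnings <- c(warnings, "map language missing; assuming process description")
  } else if (lang != "process description") {
    stop(sprintf("unsupported map language '%s' (only process description)",
                 lang), call. = FALSE)
  }

  node_records <- list()
  port_owner <- character(0)  # port id -> glyph id

  walk_glyph <- function(node, parent_id) {
    cls_raw <- xml2::xml_attr(node, "class")
    id <- xml2::xml_attr(node, "id")
    if (!is.na(cls_raw) && cls_raw %in% SBGN_SKIP_GLYPHS) return(invisible())
    if (is.na(id)) stop("glyph without id", call. = FALSE)
    cls <- normalize_node_class(cls_raw)
    if (is.na(cls)) {
      warnings <<- c(warnings, sprintf(
        "unknown glyph class '%s' on '%s' mapped to generic", cls_raw, id))
      cls <- "generic"
    }
    comp_ref <- xml2::xml_attr(node, "compartmentRef")
    parent <- if (!is.na(comp_ref)) comp_ref else parent_id
    label_node <- xml2::xml_find_first(node, "./label")
    label <- if (!inherits(label_node, "xml_missing")) {
      lt <- xml2::xml_attr(label_node, "text")
      if (is.na(lt)) id else lt
    } else id
    bbox <- xml2::xml_find_first(node, "./bbox")
    geometry <- NULL
    if (!inherits(bbox, "xml_missing")) {
      x <- as.numeric(xml2::xml_attr(bbox, "x"))
      y <- as.numeric(xml2::xml_attr(bbox, "y"))
      w <- as.numeric(xml2::xml_attr(bbox, "w"))
      h <- as.numeric(xml2::xml_attr(bbox, "h"))
      if (all(is.finite(c(x, y, w, h))) && w > 0 && h > 0) {
        geometry <- list(x = x + w / 2, y = y + h / 2, w = w, h = h)
      }
    }
    node_records[[length(node_records) + 1L]] <<- list(
      id = id, label = label, class = cls, parent = parent,
      geometry = geometry)
    for (p in xml2::xml_find_all(node, "./port")) {
      pid <- xml2::xml_attr(p, "id")
      if (!is.na(pid)) port_owner[pid] <<- id
    }
    for (sub in xml2::xml_find_all(node, "./glyph")) {
      walk_glyph(sub, id)
    }
    invisible()
  }
  for (glyph in xml2::xml_find_all(map, "./glyph")) {
    walk_glyph(glyph, NULL)
  }

  node_ids_present <- vapply(node_records, `[[`, character(1), "id")
  resolve_endpoint <- function(ref, arc_id) {
    if (ref %in% node_ids_present) return(ref)
    if (ref %in% names(port_owner)) return(port_owner[[ref]])
    stop(sprintf("arc '%s' endpoint '%s' cannot be resolved", arc_id, ref),
         call. = FALSE)
  }

  edge_records <- list()
  auto_i <- 0L
  for (arc in xml2::xml_find_all(map, "./arc")) {
    id <- xml2::xml_attr(arc, "id")
    if (is.na(id)) {
      id <- sprintf("a%d", auto_i)
      auto_i <- auto_i + 1L
    }
    cls_raw <- xml2::xml_attr(arc, "class")
    cls <- normalize_edge_class(cls_raw)
    if (is.na(cls)) {
      warnings <- c(warnings, sprintf(
        "unknown arc class '%s' on '%s' mapped to generic", cls_raw, id))
      cls <- "generic"
    }
    src <- xml2::xml_attr(arc, "source")
    tgt <- xml2::xml_attr(arc, "target")
    if (is.na(src) || is.na(tgt)) {
      stop(sprintf("arc '%s' lacks source or target", id), call. = FALSE)
    }
    edge_records[[length(edge_records) + 1L]] <- list(
      id = id, source = resolve_endpoint(src, id),
      target = resolve_endpoint(tgt, id), class = cls)
  }
  g <- build_graph_from_records(node_records, edge_records)
  new_parse_report(validate_pathway_graph(g), warnings, "sbgnml")
}

# SBGN class spellings for the writer (inverse of normalize_node_class).
sbgn_class_name <- function(class) {
  switch(class,
         nucleic_acid_feature = "nucleic acid feature",
         unspecified_entity = "unspecified entity",
         source_sink = "source and sink",
         generic = "unspecified entity",
         class)
}

#' Write a pathway graph as SBGNML (process description)
#'
#' Compartment membership is written as `compartmentRef`; complex membership
#' as glyph nesting. Center geometry is converted back to the standard's
#' top-left bbox corner. `generic` nodes are written as unspecified entities.
#'
#' @param graph A `pathway_graph`.
#' @return SBGNML text.
#' @export
write_sbgnml <- function(graph) {
  doc <- xml2::xml_new_root("sbgn", xmlns = "http://sbgn.org/libsbgn/0.2")
  map <- xml2::xml_add_child(doc, "map", language = "process description")

  emit_glyph <- function(parent_xml, n, compartment_ref) {
    attrs <- list(class = sbgn_class_name(n$class), id = n$id)
    if (!is.null(compartment_ref)) attrs$compartmentRef <- compartment_ref
    glyph <- do.call(xml2::xml_add_child,
                     c(list(parent_xml, "glyph"), attrs))
    xml2::xml_add_child(glyph, "label", text = n$label)
    if (!is.null(n$geometry)) {
      gm <- n$geometry
      xml2::xml_add_child(glyph, "bbox",
                          x = format(gm$x - gm$w / 2), y = format(gm$y - gm$h / 2),
                          w = format(gm$w), h = format(gm$h))
    }
    glyph
  }

  emitted <- new.env(parent = emptyenv())
  emit_tree <- function(id, parent_xml, compartment_ref) {
    n <- graph$nodes[[id]]
    glyph <- emit_glyph(parent_xml, n, compartment_ref)
    for (kid in graph$children[[id]]) {
      kn <- graph$nodes[[kid]]
      if (n$class == "compartment") {
        # compartment members are top-level glyphs with compartmentRef
        emit_tree(kid, map, id)
      } else {
        emit_tree(kid, glyph, NULL)
      }
    }
    assign(id, TRUE, envir = emitted)
  }
  roots <- node_ids(graph)[vapply(graph$nodes, function(n) is.na(n$parent),
                                  logical(1))]
  # compartments first so compartmentRef targets precede their referents
  root_order <- c(
    roots[vapply(roots, function(r) graph$nodes[[r]]$class == "compartment",
                 logical(1))],
    roots[vapply(roots, function(r) graph$nodes[[r]]$class != "compartment",
                 logical(1))]
  )
  for (r in root_order) emit_tree(r, map, NULL)
  for (e in graph$edges) {
    xml2::xml_add_child(map, "arc", class = e$class, id = e$id,
                        source = e$source, target = e$target)
  }
  as.character(doc)
}
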