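# Minimal, extensible SBO term mapping used by the SBML reader.
DEFAULT_SBO_MAP <- c(
  "SBO:0000247" = "simple_chemical",   # simple chemical
  "SBO:0000253" = "complex",           # non-covalent complex
  "SBO:0000250" = "nucleic_acid_feature",
  "SBO:0000245" = "macromolecule"
)

#' Read a pathway graph from SBML (Level 2/3 core)
#'
#' Species become entity nodes (class from the SBO term when recognizable,
#' else macromolecule); each reaction becomes a process node with consumption
#' edges from reactants, production edges to products and modulation edges
#' from modifiers. Compartments become compound nodes; a species' parent is
#' its compartment, and L2 `outside` references nest compartments. A
#' compartment carrying the non-covalent-complex SBO term is read back as a
#' complex node. Layout-package coordinates are adopted when present.
#' Reversible reactions are treated as irreversible in the stated direction,
#' with a warning.
#'
#' @param text SBML document text.
#' @param sbo_map Named character vector mapping SBO terms to node classes;
#'   extend to recognize more terms.
#' @return A `parse_report`.
#' @export
read_sbml <- function(text, sbo_map = DEFAULT_SBO_MAP) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") {
    stop("not an SBML document (root is not <sbml>)", call. = FALSE)
  }
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) {
    stop("SBML document has no <model>", call. = FALSE)
  }
  warnings <- character(0)
  node_records <- list()
  species_ids <- character(0)

  name_or_id <- function(el, id) {
    nm <- xml2::xml_attr(el, "name")
    if (is.na(nm) || !nzchar(nm)) id else nm
  }
  class_from_sbo <- function(el, default) {
    term <- xml2::xml_attr(el, "sboTerm")
    if (!is.na(term) && term %in% names(sbo_map)) sbo_map[[term]] else default
  }

  for (comp in xml2::xml_find_all(model, "./listOfCompartments/compartment")) {
    id <- xml2::xml_attr(comp, "id")
    outside <- xml2::xml_attr(comp, "outside")
    node_records[[length(node_records) + 1L]] <- list(
      id = id, label = name_or_id(comp, id),
      class = class_from_sbo(comp, "compartment"),
      parent = if (is.na(outside)) NULL else outside, geometry = NULL)
  }
  for (sp in xml2::xml_find_all(model, "./listOfSpecies/species")) {
    id <- xml2::xml_attr(sp, "id")
    comp <- xml2::xml_attr(sp, "compartment")
    species_ids <- c(species_ids, id)
    node_records[[length(node_records) + 1L]] <- list(
      id = id, label = name_or_id(sp, id),
      class = class_from_sbo(sp, "macromolecule"),
      parent = if (is.na(comp)) NULL else comp, geometry = NULL)
  }

  edge_records <- list()
  for (rxn in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rxn, "id")
    node_records[[length(node_records) + 1L]] <- list(
      id = rid, label = name_or_id(rxn, rid), class = "process",
      parent = NULL, geometry = NULL)
    if (identical(xml2::xml_attr(rxn, "reversible"), "true")) {
      warnings <- c(warnings, sprintf(
        "reaction '%s': reversibility ignored (treated as irreversible)", rid))
    }
    ref_species <- function(ref) {
      s <- xml2::xml_attr(ref, "species")
      if (is.na(s) || !(s %in% species_ids)) {
        stop(sprintf("reaction '%s' references unknown species '%s'", rid, s),
             call. = FALSE)
      }
      s
    }
    i <- 0L
    for (ref in xml2::xml_find_all(rxn, "./listOfReactants/speciesReference")) {
      edge_records[[length(edge_records) + 1L]] <- list(
        id = sprintf("%s_c%d", rid, i), source = ref_species(ref),
        target = rid, class = "consumption")
      i <- i + 1L
    }
    i <- 0L
    for (ref in xml2::xml_find_all(rxn, "./listOfProducts/speciesReference")) {
      edge_records[[length(edge_records) + 1L]] <- list(
        id = sprintf("%s_p%d", rid, i), source = rid,
        target = ref_species(ref), class = "production")
      i <- i + 1L
    }
    i <- 0L
    for (ref in xml2::xml_find_all(
        rxn, "./listOfModifiers/modifierSpeciesReference")) {
      edge_records[[length(edge_records) + 1L]] <- list(
        id = sprintf("%s_m%d", rid, i), source = ref_species(ref),
        target = rid, class = "modulation")
      i <- i + 1L
    }
  }

  g <- build_graph_from_records(node_records, edge_records)

  # layout package (SBML L3 layout): adopt bounding boxes when present.
  # Layout elements keep their namespace prefix, so match by local name.
  for (glyph_local in c("speciesGlyph", "compartmentGlyph", "reactionGlyph")) {
    glyph_xpath <- sprintf(".//*[local-name()='%s']", glyph_local)
    for (gl in xml2::xml_find_all(model, glyph_xpath)) {
      ref <- xml2::xml_attr(gl, "species")
      if (is.na(ref)) ref <- xml2::xml_attr(gl, "compartment")
      if (is.na(ref)) ref <- xml2::xml_attr(gl, "reaction")
      if (is.na(ref) || is.null(g$nodes[[ref]])) next
      pos <- xml2::xml_find_first(gl, ".//*[local-name()='position']")
      dim <- xml2::xml_find_first(gl, ".//*[local-name()='dimensions']")
      if (inherits(pos, "xml_missing") || inherits(dim, "xml_missing")) next
      x <- as.numeric(xml2::xml_attr(pos, "x"))
      y <- as.numeric(xml2::xml_attr(pos, "y"))
      w <- as.numeric(xml2::xml_attr(dim, "width"))
      h <- as.numeric(xml2::xml_attr(dim, "height"))
      if (all(is.finite(c(x, y, w, h))) && w > 0 && h > 0) {
        g <- set_geometry(g, ref, x + w / 2, y + h / 2, w, h)
      }
    }
  }
  new_parse_report(validate_pathway_graph(g), warnings, "sbml")
}

#' Write a pathway graph as SBML (Level 2 Version 4)
#'
#' Level 2 is used because its `outside` attribute is the only core-SBML way
#' to express compartment nesting. Molecular complexes are encoded as
#' compartments carrying SBO:0000253 (non-covalent complex); simple chemicals
#' carry SBO:0000247 so their class survives the round trip. Every process
#' node becomes a reaction whose consumption/production/modulation edges
#' become reactants/products/modifiers. Non-process, non-compound nodes
#' become species.
#'
#' @param graph A `pathway_graph` in which every arc has exactly one process
#'   endpoint (the reader cannot represent entity-entity arcs).
#' @return SBML text.
#' @export
write_sbml <- function(graph) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "pathway")

  is_comp <- vapply(graph$nodes, function(n) n$class %in% COMPOUND_CLASSES,
                    logical(1))
  is_proc <- vapply(graph$nodes,
                    function(n) n$class %in% c("process", "association",
                                               "dissociation"),
                    logical(1))
  comps <- node_ids(graph)[is_comp]
  procs <- node_ids(graph)[is_proc]
  specs <- setdiff(node_ids(graph), c(comps, procs))

  if (length(comps)) {
    loc <- xml2::xml_add_child(model, "listOfCompartments")
    for (id in comps) {
      n <- graph$nodes[[id]]
      attrs <- list(id = id, name = n$label)
      if (!is.na(n$parent)) attrs$outside <- n$parent
      if (n$class == "complex") attrs$sboTerm <- "SBO:0000253"
      do.call(xml2::xml_add_child, c(list(loc, "compartment"), attrs))
    }
  }
  if (length(specs)) {
    los <- xml2::xml_add_child(model, "listOfSpecies")
    for (id in specs) {
      n <- graph$nodes[[id]]
      attrs <- list(id = id, name = n$label)
      attrs$compartment <- if (!is.na(n$parent)) n$parent else "default"
      if (n$class == "simple_chemical") attrs$sboTerm <- "SBO:0000247"
      do.call(xml2::xml_add_child, c(list(los, "species"), attrs))
    }
    if (any(vapply(specs, function(id) is.na(graph$nodes[[id]]$parent),
                   logical(1))) && !("default" %in% comps)) {
      loc <- xml2::xml_find_first(model, "./listOfCompartments")
      if (inherits(loc, "xml_missing")) {
        loc <- xml2::xml_add_child(model, "listOfCompartments", .where = 0)
      }
      xml2::xml_add_child(loc, "compartment", id = "default", name = "default")
    }
  }
  if (length(procs)) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    for (id in procs) {
      n <- graph$nodes[[id]]
      rxn <- xml2::xml_add_child(lor, "reaction", id = id, name = n$label,
                                 reversible = "false")
      ins <- list(); outs <- list(); mods <- list()
      for (e in graph$edges) {
        if (e$target == id && e$class %in% c("consumption", "generic")) {
          ins <- c(ins, e$source)
        } else if (e$source == id) {
          outs <- c(outs, e$target)
        } else if (e$target == id) {
          mods <- c(mods, e$source)
        }
      }
      if (length(ins)) {
        lr <- xml2::xml_add_child(rxn, "listOfReactants")
        for (s in ins) xml2::xml_add_child(lr, "speciesReference", species = s)
      }
      if (length(outs)) {
        lp <- xml2::xml_add_child(rxn, "listOfProducts")
        for (s in outs) xml2::xml_add_child(lp, "speciesReference", species = s)
      }
      if (length(mods)) {
        lm <- xml2::xml_add_child(rxn, "listOfModifiers")
        for (s in mods) {
          xml2::xml_add_child(lm, "modifierSpeciesReference", species = s)
        }
      }
    }
  }
  as.character(doc)
}
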