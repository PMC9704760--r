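STYLE_SCHEMES <- c("red_blue", "single_color")
IMAGE_FORMATS <- c("svg", "png", "jpg")
DEFAULT_ROLE_COLORS <- c(seed = "#00CC00", result = "#FF4444",
                         link = "#FFD700")

#' Style options for image construction
#'
#' @param scheme `"red_blue"` (red simple chemicals, blue macromolecules) or
#'   `"single_color"` (per-class lightness shades derived from
#'   `base_color`).
#' @param base_color Hex color driving the `single_color` scheme.
#' @param background Hex background color, or `NULL` for transparent. JPG
#'   output cannot be transparent; a white background is substituted with a
#'   warning.
#' @param image_format `"svg"`, `"png"` or `"jpg"`.
#' @param width,height Output dimensions in px; the drawing is letterboxed
#'   to preserve its aspect ratio.
#' @param result_only Crop the image to the highlighted elements (plus
#'   margin) instead of the whole map.
#' @param role_colors Named hex colors for the highlight roles `seed`,
#'   `result` and `link`.
#' @param highlight_width_range Two-element `c(min, max)` px range; a node's
#'   highlight thickness in `[0, 1]` maps linearly onto it.
#' @return A `style_options` list.
#' @export
style_options <- function(scheme = "red_blue", base_color = "#888888",
                          background = NULL, image_format = "svg",
                          width = 1000, height = 800, result_only = FALSE,
                          role_colors = DEFAULT_ROLE_COLORS,
                          highlight_width_range = c(2, 10)) {
  scheme <- match.arg(scheme, STYLE_SCHEMES)
  image_format <- match.arg(image_format, IMAGE_FORMATS)
  stopifnot(width > 0, height > 0, length(highlight_width_range) == 2,
            highlight_width_range[1] <= highlight_width_range[2])
  check_hex(base_color)
  if (!is.null(background)) check_hex(background)
  rc <- DEFAULT_ROLE_COLORS
  rc[names(role_colors)] <- role_colors
  for (col in rc) check_hex(col)
  structure(list(scheme = scheme, base_color = base_color,
                 background = background, image_format = image_format,
                 width = width, height = height,
                 result_only = isTRUE(result_only), role_colors = rc,
                 highlight_width_range = as.numeric(highlight_width_range)),
            class = "style_options")
}

check_hex <- function(x) {
  if (!is.character(x) || length(x) != 1 ||
      !grepl("^#[0-9A-Fa-f]{6}$", x)) {
    stop(sprintf("not a hex color: '%s'", paste(x, collapse = ",")),
         call. = FALSE)
  }
  invisible(x)
}

style_options_from_list <- function(x) {
  if (is.null(x)) return(style_options())
  if (inherits(x, "style_options")) return(x)
  key_alias <- c(baseColor = "base_color", imageFormat = "image_format",
                 format = "image_format", resultOnly = "result_only",
                 roleColors = "role_colors",
                 highlightWidthRange = "highlight_width_range")
  nm <- names(x)
  nm[nm %in% names(key_alias)] <- key_alias[nm[nm %in% names(key_alias)]]
  names(x) <- nm
  unknown <- setdiff(nm, names(formals(style_options)))
  if (length(unknown)) {
    stop(sprintf("unknown image option(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(x$role_colors)) x$role_colors <- unlist(x$role_colors)
  if (!is.null(x$highlight_width_range)) {
    x$highlight_width_range <- unlist(x$highlight_width_range)
  }
  do.call(style_options, x)
}

#' Highlight specification
#'
#' @param node_roles Named character vector mapping node ids to a role among
#'   `"seed"`, `"result"`, `"link"`.
#' @param edge_ids Edge ids to paint in the link role color.
#' @param node_thickness Named numeric vector in `[0, 1]` controlling the
#'   highlight stroke width per node (centrality display); nodes without an
#'   entry use the minimum width.
#' @return A `highlight_spec` list.
#' @export
highlight_spec <- function(node_roles = character(0),
                           edge_ids = character(0),
                           node_thickness = numeric(0)) {
  if (length(node_roles)) {
    stopifnot(all(node_roles %in% c("seed", "result", "link")))
  }
  if (length(node_thickness)) {
    stopifnot(all(node_thickness >= 0 & node_thickness <= 1))
  }
  structure(list(node_roles = node_roles, edge_ids = edge_ids,
                 node_thickness = node_thickness),
            class = "highlight_spec")
}

#' Build a highlight specification from a query result
#'
#' Seeds, result nodes and connecting links get the roles a common-stream
#' figure uses (green seeds, red results, yellow links); result edges are
#' painted in the link color.
#'
#' @param result A `query_result`.
#' @return A `highlight_spec`.
#' @export
highlight_from_result <- function(result) {
  stopifnot(inherits(result, "query_result"))
  roles <- result$roles
  if (is.null(roles)) {
    roles <- stats::setNames(rep("result", length(result$result_nodes)),
                             result$result_nodes)
    roles[result$seed_nodes] <- "seed"
  }
  highlight_spec(node_roles = roles, edge_ids = result$result_edges)
}

# --- per-class style --------------------------------------------------------

hex_to_hsl <- function(hex) {
  rgb <- grDevices::col2rgb(hex)[, 1] / 255
  mx <- max(rgb); mn <- min(rgb); l <- (mx + mn) / 2
  if (mx == mn) return(c(h = 0, s = 0, l = l))
  d <- mx - mn
  s <- if (l > 0.5) d / (2 - mx - mn) else d / (mx + mn)
  h <- if (mx == rgb[1]) ((rgb[2] - rgb[3]) / d) %% 6
       else if (mx == rgb[2]) (rgb[3] - rgb[1]) / d + 2
       else (rgb[1] - rgb[2]) / d + 4
  c(h = h * 60, s = s, l = l)
}

hsl_to_hex <- function(h, s, l) {
  c1 <- (1 - abs(2 * l - 1)) * s
  x <- c1 * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c1 / 2
  rgb1 <- if (h < 60) c(c1, x, 0) else if (h < 120) c(x, c1, 0)
          else if (h < 180) c(0, c1, x) else if (h < 240) c(0, x, c1)
          else if (h < 300) c(x, 0, c1) else c(c1, 0, x)
  grDevices::rgb(rgb1[1] + m, rgb1[2] + m, rgb1[3] + m)
}

# lightness offsets per class for the single-color scheme (declared table)
SINGLE_COLOR_LIGHTNESS <- c(
  macromolecule = 0, simple_chemical = 0.12, nucleic_acid_feature = -0.08,
  unspecified_entity = 0.2, complex = -0.15, compartment = 0.3,
  process = 0.25, association = 0.25, dissociation = 0.25,
  phenotype = -0.05, source_sink = 0.35, generic = 0
)

RED_BLUE_FILLS <- c(
  macromolecule = "#2E6DB4", simple_chemical = "#D63B3B",
  nucleic_acid_feature = "#5A8FD0", unspecified_entity = "#C8D4E8",
  complex = "#9FB8DC", compartment = "#F4F6FB", process = "#E8E8E8",
  association = "#555555", dissociation = "#FFFFFF", phenotype = "#B48ACD",
  source_sink = "#FFFFFF", generic = "#CCCCCC"
)

NODE_SHAPES <- c(
  macromolecule = "rounded_rect", simple_chemical = "stadium",
  nucleic_acid_feature = "bottom_rounded_rect", unspecified_entity = "ellipse",
  complex = "cut_rect", compartment = "compartment", process = "square",
  association = "circle", dissociation = "circle", phenotype = "hexagon",
  source_sink = "circle", generic = "rect"
)

#' Per-class node style
#'
#' Deterministic mapping from node class and color scheme to shape, fill and
#' border. The red-blue scheme paints simple chemicals red and
#' macromolecules blue; the single-color scheme derives per-class lightness
#' steps from `base_color`.
#'
#' @param node_class One of [node_classes()] (unknown classes fall back to
#'   the generic style).
#' @param scheme `"red_blue"` or `"single_color"`.
#' @param base_color Hex color for the single-color scheme.
#' @return List with `shape`, `fill`, `stroke`, `stroke_width`.
#' @export
node_style <- function(node_class, scheme = "red_blue",
                       base_color = "#888888") {
  scheme <- match.arg(scheme, STYLE_SCHEMES)
  if (!node_class %in% NODE_CLASSES) node_class <- "generic"
  shape <- NODE_SHAPES[[node_class]]
  if (scheme == "red_blue") {
    fill <- RED_BLUE_FILLS[[node_class]]
  } else {
    hsl <- hex_to_hsl(base_color)
    l <- min(max(hsl[["l"]] + SINGLE_COLOR_LIGHTNESS[[node_class]], 0.05), 0.95)
    fill <- hsl_to_hex(hsl[["h"]], hsl[["s"]], l)
  }
  stroke_width <- if (node_class == "compartment") 3 else 1.5
  list(shape = shape, fill = fill, stroke = "#2B2B2B",
       stroke_width = stroke_width)
}

EDGE_MARKERS <- c(consumption = "none", production = "arrow_filled",
                  catalysis = "circle_open", stimulation = "arrow_open",
                  inhibition = "bar", modulation = "diamond_open",
                  generic = "arrow_filled")

# --- SVG assembly -----------------------------------------------------------

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) trimws(formatC(x, format = "fg", digits = 6))

# intersection of the segment (from center of `gm` toward px,py) with the
# node border; ellipse for round shapes, rectangle otherwise
border_point <- function(gm, shape, tx, ty) {
  dx <- tx - gm$x; dy <- ty - gm$y
  if (abs(dx) < 1e-9 && abs(dy) < 1e-9) return(c(gm$x, gm$y))
  if (shape %in% c("ellipse", "stadium", "circle")) {
    t <- 1 / sqrt((dx / (gm$w / 2))^2 + (dy / (gm$h / 2))^2)
  } else {
    t <- min(
      if (abs(dx) > 1e-9) (gm$w / 2) / abs(dx) else Inf,
      if (abs(dy) > 1e-9) (gm$h / 2) / abs(dy) else Inf
    )
  }
  t <- min(t, 1)
  c(gm$x + dx * t, gm$y + dy * t)
}

node_shape_svg <- function(n, st, stroke, stroke_width) {
  gm <- n$geometry
  x1 <- gm$x - gm$w / 2; y1 <- gm$y - gm$h / 2
  common <- sprintf(
    'class="node" data-id="%s" fill="%s" stroke="%s" stroke-width="%s"',
    svg_escape(n$id), st$fill, stroke, fmt_num(stroke_width))
  switch(st$shape,
    rounded_rect = , compartment = sprintf(
      '<rect %s x="%s" y="%s" width="%s" height="%s" rx="%s"/>',
      common, fmt_num(x1), fmt_num(y1), fmt_num(gm$w), fmt_num(gm$h),
      fmt_num(if (st$shape == "compartment") 12 else 6)),
    stadium = sprintf(
      '<rect %s x="%s" y="%s" width="%s" height="%s" rx="%s"/>',
      common, fmt_num(x1), fmt_num(y1), fmt_num(gm$w), fmt_num(gm$h),
      fmt_num(gm$h / 2)),
    bottom_rounded_rect = , rect = sprintf(
      '<rect %s x="%s" y="%s" width="%s" height="%s"/>',
      common, fmt_num(x1), fmt_num(y1), fmt_num(gm$w), fmt_num(gm$h)),
    ellipse = sprintf(
      '<ellipse %s cx="%s" cy="%s" rx="%s" ry="%s"/>',
      common, fmt_num(gm$x), fmt_num(gm$y), fmt_num(gm$w / 2),
      fmt_num(gm$h / 2)),
    circle = , square = sprintf(
      if (st$shape == "circle") {
        '<ellipse %s cx="%s" cy="%s" rx="%s" ry="%s"/>'
      } else {
        '<rect %s x="%s" y="%s" width="%s" height="%s"/>'
      },
      common,
      if (st$shape == "circle") fmt_num(gm$x) else fmt_num(x1),
      if (st$shape == "circle") fmt_num(gm$y) else fmt_num(y1),
      fmt_num(if (st$shape == "circle") gm$w / 2 else gm$w),
      fmt_num(if (st$shape == "circle") gm$h / 2 else gm$h)),
    cut_rect = {
      c8 <- min(gm$w, gm$h) / 5
      pts <- rbind(
        c(x1 + c8, y1), c(x1 + gm$w - c8, y1), c(x1 + gm$w, y1 + c8),
        c(x1 + gm$w, y1 + gm$h - c8), c(x1 + gm$w - c8, y1 + gm$h),
        c(x1 + c8, y1 + gm$h), c(x1, y1 + gm$h - c8), c(x1, y1 + c8))
      sprintf('<polygon %s points="%s"/>', common,
              paste(apply(pts, 1, function(p) {
                paste(fmt_num(p[1]), fmt_num(p[2]), sep = ",")
              }), collapse = " "))
    },
    hexagon = {
      pts <- rbind(
        c(x1 + gm$w * 0.25, y1), c(x1 + gm$w * 0.75, y1),
        c(x1 + gm$w, gm$y), c(x1 + gm$w * 0.75, y1 + gm$h),
        c(x1 + gm$w * 0.25, y1 + gm$h), c(x1, gm$y))
      sprintf('<polygon %s points="%s"/>', common,
              paste(apply(pts, 1, function(p) {
                paste(fmt_num(p[1]), fmt_num(p[2]), sep = ",")
              }), collapse = " "))
    },
    sprintf('<rect %s x="%s" y="%s" width="%s" height="%s"/>',
            common, fmt_num(x1), fmt_num(y1), fmt_num(gm$w), fmt_num(gm$h))
  )
}

svg_markers <- function(link_color) {
  tpl <- paste0(
    '<marker id="%s" viewBox="0 0 10 10" refX="9" refY="5" ',
    'markerWidth="8" markerHeight="8" orient="auto-start-reverse">%s</marker>')
  paste0(
    "<defs>",
    sprintf(tpl, "arrow_filled",
            '<polygon points="0,0 10,5 0,10" fill="#2B2B2B"/>'),
    sprintf(tpl, "arrow_open",
            paste0('<polygon points="0,0 10,5 0,10" fill="white" ',
                   'stroke="#2B2B2B"/>')),
    sprintf(tpl, "circle_open",
            paste0('<circle cx="5" cy="5" r="4" fill="white" ',
                   'stroke="#2B2B2B"/>')),
    sprintf(tpl, "diamond_open",
            paste0('<polygon points="0,5 5,0 10,5 5,10" fill="white" ',
                   'stroke="#2B2B2B"/>')),
    sprintf(tpl, "bar",
            '<line x1="8" y1="0" x2="8" y2="10" stroke="#2B2B2B" stroke-width="2"/>'),
    "</defs>")
}

#' Render a pathway graph as SVG
#'
#' One shape element per node (compounds drawn beneath their members, in
#' containment preorder), one path per edge with a class-specific arrowhead
#' (production: filled arrow; catalysis: open circle; inhibition: bar;
#' stimulation: open arrow; consumption: none), and centered labels
#' (truncated with an ellipsis when wider than 90% of the node). Highlighted
#' nodes get a role-colored stroke whose width maps linearly from the node's
#' highlight thickness onto `highlight_width_range`; highlighted edges take
#' the link role color. The viewBox covers the whole map plus margin, or
#' only the highlighted elements when `result_only` is set.
#'
#' @param graph A `pathway_graph` in which every node has geometry.
#' @param highlight Optional [highlight_spec()] (or `NULL`).
#' @param style A [style_options()].
#' @return SVG 1.1 text.
#' @export
render_svg <- function(graph, highlight = NULL, style = style_options()) {
  gm_all <- geometry_map(graph)
  missing <- setdiff(node_ids(graph), names(gm_all))
  if (length(missing)) {
    stop(sprintf("node(s) without geometry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(highlight)) highlight <- highlight_spec()
  roles <- highlight$node_roles
  hw <- style$highlight_width_range

  elements <- character(0)
  order <- containment_preorder(graph)
  for (id in order) {
    n <- graph$nodes[[id]]
    st <- node_style(n$class, style$scheme, style$base_color)
    stroke <- st$stroke; swidth <- st$stroke_width
    role <- roles[id]
    if (!is.na(role) && length(role)) {
      thick <- highlight$node_thickness[id]
      if (is.na(thick) || !length(thick)) {
        thick <- if (!is.null(n$highlight_thickness)) n$highlight_thickness
                 else 0
      }
      stroke <- style$role_colors[[role]]
      swidth <- hw[1] + thick * (hw[2] - hw[1])
    } else if (!is.null(n$highlight_thickness)) {
      swidth <- hw[1] + n$highlight_thickness * (hw[2] - hw[1])
    }
    elements <- c(elements, node_shape_svg(n, st, stroke, swidth))
  }
  # labels after all shapes so they are never covered
  for (id in order) {
    n <- graph$nodes[[id]]
    gm <- n$geometry
    label <- n$label
    est_char_w <- 7  # ~ glyph advance at font-size 12
    max_chars <- max(1, floor(0.9 * gm$w / est_char_w))
    if (nchar(label) > max_chars) {
      label <- paste0(substr(label, 1, max(1, max_chars - 1)), "…")
    }
    ly <- if (n$class %in% COMPOUND_CLASSES) gm$y - gm$h / 2 + 14 else gm$y
    elements <- c(elements, sprintf(
      paste0('<text class="label" x="%s" y="%s" text-anchor="middle" ',
             'dominant-baseline="middle" font-family="Helvetica, sans-serif" ',
             'font-size="12">%s</text>'),
      fmt_num(gm$x), fmt_num(ly), svg_escape(label)))
  }
  for (e in graph$edges) {
    src <- graph$nodes[[e$source]]; tgt <- graph$nodes[[e$target]]
    sst <- node_style(src$class, style$scheme, style$base_color)
    tst <- node_style(tgt$class, style$scheme, style$base_color)
    p1 <- border_point(src$geometry, sst$shape, tgt$geometry$x, tgt$geometry$y)
    p2 <- border_point(tgt$geometry, tst$shape, src$geometry$x, src$geometry$y)
    hl <- e$id %in% highlight$edge_ids
    stroke <- if (hl) style$role_colors[["link"]] else "#2B2B2B"
    swidth <- if (hl) 3 else 1.5
    marker <- EDGE_MARKERS[[e$class]]
    marker_attr <- if (marker != "none") {
      sprintf(' marker-end="url(#%s)"', marker)
    } else ""
    elements <- c(elements, sprintf(
      '<path class="edge" data-id="%s" d="M %s %s L %s %s" stroke="%s" stroke-width="%s" fill="none"%s/>',
      svg_escape(e$id), fmt_num(p1[1]), fmt_num(p1[2]), fmt_num(p2[1]),
      fmt_num(p2[2]), stroke, fmt_num(swidth), marker_attr))
  }

  # view bounds
  margin <- 20
  scope_ids <- if (style$result_only && length(roles)) {
    intersect(names(roles), node_ids(graph))
  } else node_ids(graph)
  if (length(scope_ids)) {
    boxes <- gm_all[scope_ids]
    x1 <- min(vapply(boxes, function(b) b$x - b$w / 2, numeric(1))) - margin
    y1 <- min(vapply(boxes, function(b) b$y - b$h / 2, numeric(1))) - margin
    x2 <- max(vapply(boxes, function(b) b$x + b$w / 2, numeric(1))) + margin
    y2 <- max(vapply(boxes, function(b) b$y + b$h / 2, numeric(1))) + margin
  } else {
    x1 <- 0; y1 <- 0; x2 <- style$width; y2 <- style$height
  }
  bg <- if (!is.null(style$background)) {
    sprintf('<rect class="background" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
            fmt_num(x1), fmt_num(y1), fmt_num(x2 - x1), fmt_num(y2 - y1),
            style$background)
  } else ""
  paste0(
    sprintf(paste0(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" ',
      'height="%s" viewBox="%s %s %s %s" preserveAspectRatio="xMidYMid meet">'),
      fmt_num(style$width), fmt_num(style$height), fmt_num(x1), fmt_num(y1),
      fmt_num(x2 - x1), fmt_num(y2 - y1)),
    svg_markers(style$role_colors[["link"]]),
    bg,
    paste(elements, collapse = ""),
    "</svg>")
}
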