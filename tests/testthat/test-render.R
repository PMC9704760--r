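laid_out_fixture <- function(seed = 7) {
  g <- generate_pathway(fixture_spec(6, 3, 2, 1, seed = seed))
  apply_geometry(g, layout_pathway(g, layout_options(seed = 1,
                                                     max_iterations = 300)))
}

count_pattern <- function(svg, pattern) {
  length(gregexpr(pattern, svg, fixed = TRUE)[[1]]) -
    (gregexpr(pattern, svg, fixed = TRUE)[[1]][1] == -1)
}

test_that("node_style is deterministic and honors the red-blue scheme", {
  expect_identical(node_style("macromolecule"), node_style("macromolecule"))
  rb_chem <- node_style("simple_chemical", "red_blue")
  rb_macro <- node_style("macromolecule", "red_blue")
  chem_rgb <- grDevices::col2rgb(rb_chem$fill)[, 1]
  macro_rgb <- grDevices::col2rgb(rb_macro$fill)[, 1]
  expect_gt(chem_rgb["red"], chem_rgb["blue"])    # simple chemicals: red
  expect_gt(macro_rgb["blue"], macro_rgb["red"])  # macromolecules: blue

  sc <- node_style("generic", "single_color", "#888888")
  expect_equal(toupper(sc$fill), "#888888")  # zero lightness step
  lighter <- node_style("process", "single_color", "#888888")
  expect_gt(grDevices::col2rgb(lighter$fill)[1, 1], 136)

  # unknown class falls back to the generic shape, no error
  expect_equal(node_style("not_a_class")$shape, "rect")
})

test_that("render_svg emits one shape per node and one path per edge", {
  g <- laid_out_fixture()
  svg <- render_svg(g, NULL, style_options())
  doc <- xml2::read_xml(svg)  # well-formed
  xml2::xml_ns_strip(doc)
  shapes <- xml2::xml_find_all(doc, ".//*[@class='node']")
  edges <- xml2::xml_find_all(doc, ".//path[@class='edge']")
  expect_length(shapes, n_nodes(g))
  expect_length(edges, n_edges(g))

  # z-order: compound shapes precede all of their descendants' shapes
  order <- vapply(shapes, function(s) xml2::xml_attr(s, "data-id"),
                  character(1))
  for (id in node_ids(g)) {
    for (d in descendants(g, id)) {
      expect_lt(which(order == id), which(order == d))
    }
  }

  expect_error(render_svg(generate_pathway(fixture_spec(2, 1, 0, 0)) |>
                            (\(x) { x$nodes[[1]]$geometry <- NULL; x })(),
                          NULL, style_options()),
               "without geometry")
})

test_that("empty graph renders a valid background-only SVG", {
  svg <- render_svg(pathway_graph(), NULL,
                    style_options(background = "#FFFFFF"))
  doc <- xml2::read_xml(svg)
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, ".//*[@class='node']"), 0)
  expect_length(xml2::xml_find_all(doc, ".//rect[@class='background']"), 1)
})

test_that("highlight thickness maps linearly onto the width range", {
  g <- pathway_graph()
  g <- add_node(g, "lo"); g <- add_node(g, "hi")
  g <- set_geometry(g, "lo", 0, 0, 40, 40)
  g <- set_geometry(g, "hi", 100, 0, 40, 40)
  hl <- highlight_spec(
    node_roles = c(lo = "result", hi = "result"),
    node_thickness = c(lo = 0, hi = 1))
  svg <- render_svg(g, hl, style_options(highlight_width_range = c(2, 10)))
  doc <- xml2::read_xml(svg); xml2::xml_ns_strip(doc)
  w_of <- function(id) as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, sprintf(".//*[@data-id='%s']", id)),
    "stroke-width"))
  expect_equal(w_of("lo"), 2)
  expect_equal(w_of("hi"), 10)
})

test_that("highlighting is purely additive", {
  g <- laid_out_fixture()
  base <- render_svg(g, NULL, style_options())
  with_empty <- render_svg(g, highlight_spec(), style_options())
  expect_identical(base, with_empty)
})

test_that("role colors follow the seed/result/link scheme", {
  g <- graph_from_arrows(c("A->X", "B->X"))
  g <- apply_geometry(g, layout_pathway(g, layout_options(seed = 2,
                                                          max_iterations = 200)))
  r <- common_stream(g, c("A", "B"), "downstream", 1)
  svg <- render_svg(g, highlight_from_result(r), style_options())
  doc <- xml2::read_xml(svg); xml2::xml_ns_strip(doc)
  stroke_of <- function(id) xml2::xml_attr(
    xml2::xml_find_first(doc, sprintf(".//*[@data-id='%s']", id)), "stroke")
  expect_equal(stroke_of("A"), "#00CC00")
  expect_equal(stroke_of("B"), "#00CC00")
  expect_equal(stroke_of("X"), "#FF4444")
  # highlighted edges in link yellow
  expect_equal(stroke_of("e1"), "#FFD700")
})

test_that("result_only crops the viewBox to the highlighted elements", {
  g <- pathway_graph()
  for (id in c("A", "B", "far")) g <- add_node(g, id)
  g <- add_edge(g, "e1", "A", "B")
  g <- set_geometry(g, "A", 0, 0, 40, 40)
  g <- set_geometry(g, "B", 60, 0, 40, 40)
  g <- set_geometry(g, "far", 2000, 2000, 40, 40)
  hl <- highlight_spec(node_roles = c(A = "seed", B = "result"),
                       edge_ids = "e1")
  vb <- function(svg) as.numeric(strsplit(
    xml2::xml_attr(xml2::read_xml(svg), "viewBox"), " ")[[1]])
  full <- vb(render_svg(g, hl, style_options(result_only = FALSE)))
  crop <- vb(render_svg(g, hl, style_options(result_only = TRUE)))
  expect_gt(full[3], 2000)          # full map spans to the far node
  expect_lt(crop[3], 200)           # crop covers only A, B + margin
})

test_that("rasterize produces PNGs of the requested size honoring alpha", {
  g <- laid_out_fixture()
  svg <- render_svg(g, NULL, style_options())
  st <- style_options(image_format = "png", width = 320, height = 240)
  bytes <- rasterize(svg, st)
  info <- pathmapr:::png_header_info(bytes)
  expect_equal(info$width, 320)
  expect_equal(info$height, 240)
  expect_equal(info$color_type, 6)  # RGBA: alpha channel kept

  # transparent empty map really is transparent (decode via PIL oracle)
  empty_svg <- render_svg(pathway_graph(), NULL, style_options())
  empty_png <- rasterize(empty_svg, st)
  tmp <- withr::local_tempfile(fileext = ".png")
  writeBin(empty_png, tmp)
  out <- system2("python", c("-c", shQuote(paste0(
    "from PIL import Image; im = Image.open('", tmp, "').convert('RGBA'); ",
    "print(im.getextrema()[3])"))), stdout = TRUE)
  expect_match(out, "\\(0, 0\\)")  # alpha extrema: fully transparent
})

test_that("jpg substitutes an opaque background with a warning", {
  g <- laid_out_fixture()
  svg <- render_svg(g, NULL, style_options())
  st <- style_options(image_format = "jpg", width = 200, height = 150)
  expect_warning(bytes <- rasterize(svg, st), "cannot be transparent")
  expect_identical(as.integer(bytes[1:2]), c(255L, 216L))  # JPEG SOI marker
  expect_error(rasterize(svg, style_options(image_format = "svg")),
               "png.*jpg")
  expect_error(rasterize("<div/>",
                         style_options(image_format = "png")), "not an SVG")
})

test_that("style option parsing validates colors and rejects unknown keys", {
  expect_error(style_options(base_color = "red"), "hex")
  expect_error(style_options(width = 0))
  expect_error(style_options_from_list(list(bogus = 1)), "unknown image")
  so <- style_options_from_list(list(imageFormat = "png",
                                     baseColor = "#FF0000"))
  expect_equal(so$image_format, "png")
  expect_equal(so$base_color, "#FF0000")
})
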