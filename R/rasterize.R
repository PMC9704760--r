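# Raster output. No SVG rasterizer library is assumed: this interprets the
# element subset that render_svg() emits (rect, ellipse, polygon, path,
# line, text) and redraws it on R's cairo bitmap devices. Arrowhead markers
# are approximated by the plain edge path.

parse_svg_color <- function(x, default = NA) {
  if (is.null(x) || is.na(x) || x == "none") return(default)
  x
}

#' Rasterize SVG text to PNG or JPG bytes
#'
#' Draws the SVG subset produced by [render_svg()] at the requested
#' dimensions, preserving the aspect ratio by letterboxing. PNG honors
#' transparency; JPG cannot, so a white background is substituted (with a
#' warning) when none is set.
#'
#' @param svg_text SVG text from [render_svg()].
#' @param style A [style_options()] whose `image_format` is `"png"` or
#'   `"jpg"`.
#' @return Raw vector of image bytes.
#' @export
rasterize <- function(svg_text, style = style_options(image_format = "png")) {
  if (style$image_format == "svg") {
    stop("rasterize() needs image_format 'png' or 'jpg'", call. = FALSE)
  }
  doc <- xml2::read_xml(svg_text)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "svg") stop("not an SVG document", call. = FALSE)
  vb <- strsplit(trimws(xml2::xml_attr(doc, "viewBox")), "\\s+")[[1]]
  vb <- as.numeric(vb)
  if (length(vb) != 4 || any(!is.finite(vb))) {
    stop("SVG lacks a usable viewBox", call. = FALSE)
  }
  W <- style$width; H <- style$height
  background <- style$background
  if (style$image_format == "jpg" && is.null(background)) {
    warning("jpg cannot be transparent; substituting white background")
    background <- "#FFFFFF"
  }

  # letterbox: fit viewBox into W x H keeping aspect
  scale <- min(W / vb[3], H / vb[4])
  off_x <- (W - vb[3] * scale) / 2
  off_y <- (H - vb[4] * scale) / 2
  ux <- function(x) off_x + (x - vb[1]) * scale
  uy <- function(y) off_y + (y - vb[2]) * scale

  path <- tempfile(fileext = paste0(".", style$image_format))
  on.exit(unlink(path), add = TRUE)
  if (style$image_format == "png") {
    grDevices::png(path, width = W, height = H, type = "cairo-png",
                   bg = if (is.null(background)) "transparent" else background)
  } else {
    grDevices::jpeg(path, width = W, height = H, type = "cairo",
                    bg = background, quality = 90)
  }
  ok <- FALSE
  tryCatch({
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, W), ylim = c(H, 0))  # y grows downward

    num_attr <- function(el, name, default = 0) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(el, name)))
      if (is.na(v)) default else v
    }
    lwd_of <- function(el) max(0.5, num_attr(el, "stroke-width", 1) * scale)

    for (el in xml2::xml_find_all(doc, ".//*")) {
      tag <- xml2::xml_name(el)
      fill <- parse_svg_color(xml2::xml_attr(el, "fill"))
      stroke <- parse_svg_color(xml2::xml_attr(el, "stroke"))
      if (tag == "rect") {
        x <- num_attr(el, "x"); y <- num_attr(el, "y")
        w <- num_attr(el, "width"); h <- num_attr(el, "height")
        graphics::rect(ux(x), uy(y + h), ux(x + w), uy(y),
                       col = fill, border = stroke, lwd = lwd_of(el))
      } else if (tag == "ellipse") {
        cx <- num_attr(el, "cx"); cy <- num_attr(el, "cy")
        rx <- num_attr(el, "rx"); ry <- num_attr(el, "ry")
        theta <- seq(0, 2 * pi, length.out = 64)
        graphics::polygon(ux(cx + rx * cos(theta)), uy(cy + ry * sin(theta)),
                          col = fill, border = stroke, lwd = lwd_of(el))
      } else if (tag == "polygon" &&
                 !identical(xml2::xml_name(xml2::xml_parent(el)), "marker")) {
        pts <- strsplit(trimws(xml2::xml_attr(el, "points")), "[ ,]+")[[1]]
        pts <- matrix(as.numeric(pts), ncol = 2, byrow = TRUE)
        graphics::polygon(ux(pts[, 1]), uy(pts[, 2]),
                          col = fill, border = stroke, lwd = lwd_of(el))
      } else if (tag == "path") {
        d <- xml2::xml_attr(el, "d")
        nums <- as.numeric(strsplit(trimws(gsub("[MLZz]", " ", d)),
                                    "[ ,]+")[[1]])
        nums <- nums[is.finite(nums)]
        if (length(nums) >= 4) {
          xs <- nums[seq(1, length(nums), 2)]
          ys <- nums[seq(2, length(nums), 2)]
          graphics::lines(ux(xs), uy(ys),
                          col = if (is.na(stroke)) "#000000" else stroke,
                          lwd = lwd_of(el))
        }
      } else if (tag == "line" &&
                 !identical(xml2::xml_name(xml2::xml_parent(el)), "marker")) {
        graphics::segments(ux(num_attr(el, "x1")), uy(num_attr(el, "y1")),
                           ux(num_attr(el, "x2")), uy(num_attr(el, "y2")),
                           col = if (is.na(stroke)) "#000000" else stroke,
                           lwd = lwd_of(el))
      } else if (tag == "text") {
        fs <- num_attr(el, "font-size", 12) * scale
        graphics::text(ux(num_attr(el, "x")), uy(num_attr(el, "y")),
                       labels = xml2::xml_text(el),
                       cex = fs / 12, col = "#000000")
      }
    }
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("rasterization failed", call. = FALSE)
  readBin(path, "raw", n = file.info(path)$size)
}

# PNG IHDR introspection (used by tests and sanity checks): width, height,
# bit depth, color type, without decoding pixel data.
png_header_info <- function(bytes) {
  sig <- as.integer(bytes[1:8])
  if (!identical(sig, c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))) {
    stop("not a PNG byte stream", call. = FALSE)
  }
  be32 <- function(i) sum(as.integer(bytes[i:(i + 3)]) * c(2^24, 2^16, 2^8, 1))
  list(width = be32(17), height = be32(21),
       bit_depth = as.integer(bytes[25]),
       color_type = as.integer(bytes[26]))
}
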