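FILE_FORMATS <- c("sbgnml", "sbml", "graphml", "json")
QUERY_TYPES <- c("neighborhood", "common_stream", "paths_between",
                 "paths_from_to", "shortest_path", CENTRALITY_MEASURES)

#' Read a pathway map in any supported format
#'
#' @param text Map content.
#' @param format One of `"sbgnml"`, `"sbml"`, `"graphml"`, `"json"`.
#' @return A `parse_report`.
#' @export
read_pathway <- function(text, format) {
  format <- match.arg(format, FILE_FORMATS)
  switch(format,
         sbgnml = read_sbgnml(text),
         sbml = read_sbml(text),
         graphml = read_graphml(text),
         json = read_json_elements(text))
}

run_query <- function(graph, qo) {
  type <- qo[["type", exact = TRUE]]
  if (is.null(type) || !type %in% QUERY_TYPES) {
    stop(sprintf("unknown query type '%s'", paste(type, collapse = ",")),
         call. = FALSE)
  }
  pick <- function(name, default) {
    v <- qo[[name, exact = TRUE]]
    if (is.null(v)) default else v
  }
  direction <- pick("direction", "downstream")
  k <- as.numeric(pick("k", Inf))
  d <- as.integer(pick("d", 0L))
  sources <- unlist(pick("sources", NULL))
  targets <- unlist(pick("targets", NULL))
  if (type %in% CENTRALITY_MEASURES) {
    return(list(kind = "centrality", report = centrality(graph, type)))
  }
  result <- switch(type,
    neighborhood = neighborhood(graph, sources, direction, k),
    common_stream = common_stream(graph, sources, direction, k),
    paths_between = paths_between(graph, sources,
                                  limit_k = if (is.finite(k)) k else
                                    stop("paths_between requires k",
                                         call. = FALSE),
                                  direction = direction),
    paths_from_to = paths_from_to(graph, sources, targets, limit_k = k,
                                  additional_d = d, direction = direction),
    shortest_path = {
      if (length(sources) != 1 || length(targets) != 1) {
        stop("shortest_path needs exactly one source and one target",
             call. = FALSE)
      }
      shortest_path(graph, sources, targets, direction)
    })
  list(kind = "query", result = result)
}

query_result_summary <- function(result) {
  list(
    result_nodes = as.list(result$result_nodes),
    result_edges = as.list(result$result_edges),
    seed_nodes = as.list(result$seed_nodes),
    distances = as.list(result$distances),
    paths = lapply(result$paths, as.list),
    roles = as.list(result$roles)
  )
}

#' Handle one layout/query/image request
#'
#' The processing pipeline mirrors the service contract: parse the map,
#' run the graph query (if requested), apply the layout (if requested),
#' highlight the query result, and construct the image (if requested). All
#' three operations are optional, but at least one must be requested.
#'
#' @param request List with fields `file_format` (one of
#'   [read_pathway()]'s formats), `file_content` (map text), and any of
#'   `layout_options` (list or `TRUE` for defaults), `image_options`,
#'   `query_options` (list with `type`, `sources`, and optionally `targets`,
#'   `k`, `d`, `direction`).
#' @return A `service_response` list with fields `layout` (JSON text or
#'   `NULL`), `image` (SVG text or raw bytes or `NULL`), `query_result`
#'   (summary list or `NULL`), `warnings`, `errors`. `errors` non-empty
#'   means no payload fields are set.
#' @export
handle_request <- function(request) {
  respond_error <- function(msgs) {
    structure(list(layout = NULL, image = NULL, query_result = NULL,
                   warnings = character(0), errors = as.character(msgs)),
              class = "service_response")
  }
  out <- tryCatch({
    if (is.null(request$file_content) || !nzchar(request$file_content)) {
      stop("file_content is empty", call. = FALSE)
    }
    wants_layout <- !is.null(request$layout_options) &&
      !identical(request$layout_options, FALSE)
    wants_image <- !is.null(request$image_options) &&
      !identical(request$image_options, FALSE)
    wants_query <- !is.null(request$query_options)
    if (!wants_layout && !wants_image && !wants_query) {
      stop("request must include layout, image or query options",
           call. = FALSE)
    }
    report <- read_pathway(request$file_content, request$file_format)
    g <- report$graph
    warnings <- report$warnings

    query_payload <- NULL
    highlight <- NULL
    if (wants_query) {
      qr <- run_query(g, request$query_options)
      if (qr$kind == "centrality") {
        g <- annotate_with_centrality(g, qr$report)
        query_payload <- list(measure = qr$report$measure,
                              raw = as.list(qr$report$raw),
                              normalized = as.list(qr$report$normalized))
        highlight <- highlight_spec(
          node_roles = stats::setNames(
            rep("result", length(qr$report$normalized)),
            names(qr$report$normalized)),
          node_thickness = qr$report$normalized)
      } else {
        query_payload <- query_result_summary(qr$result)
        highlight <- highlight_from_result(qr$result)
      }
    }

    layout_payload <- NULL
    if (wants_layout) {
      lo <- layout_options_from_list(
        if (isTRUE(request$layout_options)) NULL else request$layout_options)
      g <- apply_geometry(g, layout_pathway(g, lo))
      layout_payload <- write_layout_json(g)
    }

    image_payload <- NULL
    if (wants_image) {
      so <- style_options_from_list(
        if (isTRUE(request$image_options)) NULL else request$image_options)
      if (length(geometry_map(g)) < n_nodes(g)) {
        warnings <- c(warnings,
                      "map lacks coordinates; default layout applied for imaging")
        g <- apply_geometry(g, layout_pathway(g, layout_options()))
      }
      svg <- render_svg(g, highlight, so)
      image_payload <- if (so$image_format == "svg") svg else {
        withCallingHandlers(
          rasterize(svg, so),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      }
    }
    structure(list(layout = layout_payload, image = image_payload,
                   query_result = query_payload, warnings = warnings,
                   errors = character(0)),
              class = "service_response")
  }, error = function(e) respond_error(conditionMessage(e)))
  out
}

response_to_json <- function(response) {
  payload <- list(warnings = as.list(response$warnings),
                  errors = as.list(response$errors))
  if (!is.null(response$layout)) {
    payload$layout <- jsonlite::fromJSON(response$layout,
                                         simplifyVector = FALSE)
  }
  if (!is.null(response$image)) {
    payload$image <- if (is.raw(response$image)) {
      jsonlite::base64_enc(response$image)
    } else response$image
  }
  if (!is.null(response$query_result)) {
    payload$query_result <- response$query_result
  }
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

request_from_body <- function(body_text, format) {
  parsed <- jsonlite::fromJSON(body_text, simplifyVector = FALSE)
  if (!is.list(parsed) || is.null(parsed$file_content)) {
    stop("body must be JSON with a file_content field", call. = FALSE)
  }
  list(file_format = format,
       file_content = parsed$file_content,
       layout_options = if (!is.null(parsed$layoutOptions))
         parsed$layoutOptions else parsed$layout_options,
       image_options = if (!is.null(parsed$imageOptions))
         parsed$imageOptions else parsed$image_options,
       query_options = if (!is.null(parsed$queryOptions))
         parsed$queryOptions else parsed$query_options)
}

USAGE_PAGE <- paste0(
  "pathmapr service\n\n",
  "POST /{sbgnml|sbml|graphml|json} with a JSON body:\n",
  '  {"file_content": "...", "layoutOptions": {...},\n',
  '   "imageOptions": {...}, "queryOptions": {"type": "neighborhood",\n',
  '   "sources": ["id"], "k": 2}}\n\n',
  "Response: JSON with layout, image, query_result, warnings, errors.\n")

http_app <- function() {
  list(call = function(req) {
    path <- req$PATH_INFO
    if (identical(req$REQUEST_METHOD, "GET") && path %in% c("", "/")) {
      return(list(status = 200L,
                  headers = list("Content-Type" = "text/plain"),
                  body = USAGE_PAGE))
    }
    fmt <- sub("^/", "", path)
    if (!identical(req$REQUEST_METHOD, "POST") || !fmt %in% FILE_FORMATS) {
      return(list(status = 404L,
                  headers = list("Content-Type" = "application/json"),
                  body = '{"errors":["unknown endpoint"]}'))
    }
    body <- tryCatch(req$rook.input$read_lines(), error = function(e) "")
    body <- paste(body, collapse = "\n")
    request <- tryCatch(request_from_body(body, fmt), error = function(e) e)
    if (inherits(request, "error")) {
      return(list(
        status = 400L, headers = list("Content-Type" = "application/json"),
        body = as.character(jsonlite::toJSON(
          list(errors = list(conditionMessage(request))), auto_unbox = TRUE))))
    }
    response <- handle_request(request)
    status <- if (length(response$errors)) 400L else 200L
    list(status = status,
         headers = list("Content-Type" = "application/json"),
         body = response_to_json(response))
  })
}

#' Start the HTTP facade
#'
#' `POST /<format>` (one of sbgnml, sbml, graphml, json) accepts a JSON body
#' `{file_content, layoutOptions?, imageOptions?, queryOptions?}` and
#' returns the service response as JSON; `GET /` serves a usage page.
#' Unknown paths give 404, invalid bodies 400 with an error list.
#'
#' @param port TCP port.
#' @param host Interface to bind, default loopback.
#' @param blocking If `TRUE`, run the event loop until interrupted;
#'   otherwise return the `httpuv` server handle (stop it with
#'   `httpuv::stopServer()`).
#' @return The server handle (non-blocking mode).
#' @export
serve <- function(port, host = "127.0.0.1", blocking = FALSE) {
  server <- httpuv::startServer(host, port, http_app())
  if (blocking) {
    on.exit(httpuv::stopServer(server))
    message(sprintf("pathmapr service listening on %s:%d", host, port))
    while (TRUE) {
      httpuv::service(250)
    }
  }
  server
}
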