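common_stream_fixture_json <- function() {
  write_elements_json(graph_from_arrows(c("A->X", "B->X")))
}

test_that("handle_request runs the layout-only path", {
  resp <- handle_request(list(
    file_format = "json", file_content = common_stream_fixture_json(),
    layout_options = list(seed = 5, max_iterations = 200)))
  expect_length(resp$errors, 0)
  expect_false(is.null(resp$layout))
  expect_null(resp$image)
  expect_null(resp$query_result)
  parsed <- jsonlite::fromJSON(resp$layout)
  expect_setequal(names(parsed), c("A", "B", "X"))
})

test_that("handle_request combines query, layout and image", {
  resp <- handle_request(list(
    file_format = "json", file_content = common_stream_fixture_json(),
    layout_options = list(seed = 5, max_iterations = 200),
    image_options = list(image_format = "svg"),
    query_options = list(type = "common_stream", sources = list("A", "B"),
                         direction = "downstream")))
  expect_length(resp$errors, 0)
  roles <- unlist(resp$query_result$roles)
  expect_equal(roles[["A"]], "seed")
  expect_equal(roles[["X"]], "result")
  doc <- xml2::read_xml(resp$image)
  xml2::xml_ns_strip(doc)
  strokes <- vapply(c("A", "B", "X"), function(id) xml2::xml_attr(
    xml2::xml_find_first(doc, sprintf(".//*[@data-id='%s']", id)), "stroke"),
    character(1))
  expect_equal(unname(strokes), c("#00CC00", "#00CC00", "#FF4444"))
})

test_that("handle_request surfaces parse errors and leaves payloads empty", {
  resp <- handle_request(list(file_format = "sbgnml",
                              file_content = "<not-xml",
                              layout_options = list()))
  expect_gt(length(resp$errors), 0)
  expect_null(resp$layout); expect_null(resp$image)
  expect_null(resp$query_result)

  resp2 <- handle_request(list(file_format = "json",
                               file_content = common_stream_fixture_json(),
                               query_options = list(type = "bogus")))
  expect_match(resp2$errors, "unknown query type", all = FALSE)

  resp3 <- handle_request(list(file_format = "json",
                               file_content = common_stream_fixture_json()))
  expect_match(resp3$errors, "must include", all = FALSE)
})

test_that("centrality queries annotate labels and thickness in the image", {
  g <- canonical_graphs()$path3
  resp <- handle_request(list(
    file_format = "json", file_content = write_elements_json(g),
    layout_options = list(seed = 2, max_iterations = 200),
    image_options = list(image_format = "svg"),
    query_options = list(type = "betweenness")))
  expect_length(resp$errors, 0)
  expect_equal(resp$query_result$measure, "betweenness")
  expect_equal(resp$query_result$normalized$B, 1)
  # label carries the score (possibly ellipsis-truncated to node width)
  expect_match(resp$image, "B (1", fixed = TRUE)
})

test_that("handle_request is deterministic given the request", {
  req <- list(file_format = "json",
              file_content = common_stream_fixture_json(),
              layout_options = list(seed = 11, max_iterations = 200),
              image_options = list(image_format = "svg"))
  r1 <- handle_request(req)
  r2 <- handle_request(req)
  expect_identical(r1$layout, r2$layout)
  expect_identical(r1$image, r2$image)
})

test_that("the HTTP facade accepts the curl contract", {
  port <- 18000 + (Sys.getpid() %% 2000)
  srv <- serve(port)
  on.exit(httpuv::stopServer(srv), add = TRUE)
  fetch <- function(path, body = NULL, method = "POST") {
    h <- curl::new_handle(url = sprintf("http://127.0.0.1:%d%s", port, path))
    if (!is.null(body)) {
      curl::handle_setopt(h, postfields = body)
      curl::handle_setheaders(h, "Content-Type" = "application/json")
    } else if (method == "GET") {
      curl::handle_setopt(h, httpget = TRUE)
    } else {
      curl::handle_setopt(h, post = TRUE, postfields = "")
    }
    done <- NULL
    curl::multi_add(h, done = function(res) done <<- res,
                    fail = function(e) done <<- simpleError(e))
    for (i in 1:400) {
      httpuv::service(25)
      curl::multi_run(0)
      if (!is.null(done)) break
    }
    expect_false(is.null(done))
    done
  }

  body <- as.character(jsonlite::toJSON(list(
    file_content = common_stream_fixture_json(),
    layoutOptions = list(seed = 5, max_iterations = 200),
    imageOptions = list(image_format = "svg"),
    queryOptions = list(type = "common_stream", sources = list("A", "B"))),
    auto_unbox = TRUE))

  res <- fetch("/json", body)
  expect_equal(res$status_code, 200)
  payload <- jsonlite::fromJSON(rawToChar(res$content),
                                simplifyVector = FALSE)
  expect_setequal(names(payload$layout), c("A", "B", "X"))
  expect_match(payload$image, "^<svg")
  expect_equal(payload$query_result$roles$X, "result")

  # HTTP path equals the in-process path byte for byte
  direct <- handle_request(list(
    file_format = "json", file_content = common_stream_fixture_json(),
    layout_options = list(seed = 5, max_iterations = 200),
    image_options = list(image_format = "svg"),
    query_options = list(type = "common_stream", sources = list("A", "B"))))
  expect_identical(payload$image, direct$image)

  expect_equal(fetch("/bogus", body)$status_code, 404)
  expect_equal(fetch("/sbgnml", "")$status_code, 400)
  usage <- fetch("/", method = "GET")
  expect_equal(usage$status_code, 200)
  expect_match(rawToChar(usage$content), "POST /")
})

test_that("the CLI writes requested artifacts and encodes errors in codes", {
  dir <- withr::local_tempdir()
  input <- file.path(dir, "map.json")
  writeLines(common_stream_fixture_json(), input)
  svg_out <- file.path(dir, "map.svg")
  layout_out <- file.path(dir, "layout.json")

  code <- run_cli(c("--input", input, "--format", "json", "--layout",
                    "--layout-opts", '{"seed": 3, "max_iterations": 200}',
                    "--layout-out", layout_out, "--image", svg_out))
  expect_equal(code, 0L)
  expect_true(file.exists(svg_out))
  expect_true(file.exists(layout_out))
  expect_match(readLines(svg_out, n = 1), "<svg")

  # usage errors -> 2
  expect_equal(run_cli(c("--input", input, "--format", "json",
                         "--query", "paths_from_to", "--sources", "A")), 2L)
  expect_equal(run_cli(c("--format", "json")), 2L)
  expect_equal(run_cli(c("--input", input, "--format", "nope", "--layout")),
               2L)
  # processing errors -> 1
  expect_equal(run_cli(c("--input", file.path(dir, "ghost.json"),
                         "--format", "json", "--layout")), 1L)
})

test_that("CLI batch mode processes a directory of generated fixtures", {
  dir <- withr::local_tempdir()
  for (seed in 1:3) {
    g <- generate_pathway(fixture_spec(5, 2, 1, 0, seed = seed))
    writeLines(write_elements_json(g), file.path(dir, sprintf("m%d.json", seed)))
  }
  out <- file.path(dir, "img.svg")
  code <- run_cli(c("--input", dir, "--format", "json", "--layout",
                    "--layout-opts", '{"seed": 1, "max_iterations": 150}',
                    "--image", out))
  expect_equal(code, 0L)
  written <- list.files(dir, pattern = "^img\\..*\\.svg$")
  expect_length(written, 3)
})

test_that("CLI and Rscript wrapper agree (installed entry point works)", {
  dir <- withr::local_tempdir()
  input <- file.path(dir, "map.json")
  writeLines(common_stream_fixture_json(), input)
  script <- system.file("cli", "pathmapr", package = "pathmapr")
  if (nzchar(script)) {
    out <- file.path(dir, "cli.svg")
    status <- system2("Rscript", c(script, "--input", input, "--format",
                                   "json", "--layout", "--layout-opts",
                                   shQuote('{"seed":3,"max_iterations":150}'),
                                   "--image", out),
                      stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0)
    expect_true(file.exists(out))
  } else {
    succeed("inst/cli not available under load_all; covered by run_cli tests")
  }
})
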