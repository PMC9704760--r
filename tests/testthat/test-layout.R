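fast_opts <- function(seed = 1L, ...) {
  layout_options(seed = seed, max_iterations = 400, ...)
}

overlap_area <- function(a, b) {
  ox <- min(a$x + a$w / 2, b$x + b$w / 2) - max(a$x - a$w / 2, b$x - b$w / 2)
  oy <- min(a$y + a$h / 2, b$y + b$h / 2) - max(a$y - a$h / 2, b$y - b$h / 2)
  if (ox > 0 && oy > 0) ox * oy else 0
}

fixture_pool <- list(
  small = generate_pathway(fixture_spec(6, 3, 2, 1, seed = 7)),
  medium = generate_pathway(fixture_spec(14, 7, 3, 2, seed = 11)),
  flat = generate_pathway(fixture_spec(10, 5, 0, 0, seed = 3))
)

test_that("draft placement covers every node and respects kept coordinates", {
  expect_length(draft_placement(pathway_graph()), 0)
  g <- fixture_pool$small
  d1 <- draft_placement(g, fast_opts(seed = 5))
  expect_setequal(names(d1), node_ids(g))
  for (gm in d1) {
    expect_true(all(is.finite(unlist(gm))))
    expect_gt(gm$w, 0); expect_gt(gm$h, 0)
  }
  # randomize = FALSE keeps existing geometry untouched
  d0 <- draft_placement(g, fast_opts(randomize = FALSE))
  for (id in node_ids(g)) {
    gm <- get_node(g, id)$geometry
    if (!is.null(gm) && length(g$children[[id]]) == 0) {
      expect_equal(d0[[id]]$x, gm$x)
      expect_equal(d0[[id]]$y, gm$y)
    }
  }
  # same seed, same placement
  expect_identical(d1, draft_placement(g, fast_opts(seed = 5)))
})

test_that("layout is deterministic under a fixed seed", {
  g <- fixture_pool$medium
  a <- layout_pathway(g, fast_opts(seed = 2))
  b <- layout_pathway(g, fast_opts(seed = 2))
  expect_identical(a, b)
  # a different seed is allowed to (and here does) differ
  c <- layout_pathway(g, fast_opts(seed = 3))
  expect_false(identical(a, c))
})

test_that("children stay inside their compound minus padding", {
  for (g in fixture_pool[c("small", "medium")]) {
    pad <- 10
    geom <- layout_pathway(g, fast_opts(seed = 4, compound_padding = pad))
    for (id in node_ids(g)) {
      p <- get_node(g, id)$parent
      if (is.na(p)) next
      cgm <- geom[[id]]; pgm <- geom[[p]]
      eps <- 1e-6
      expect_gte(cgm$x - cgm$w / 2, pgm$x - pgm$w / 2 + pad - eps)
      expect_lte(cgm$x + cgm$w / 2, pgm$x + pgm$w / 2 - pad + eps)
      expect_gte(cgm$y - cgm$h / 2, pgm$y - pgm$h / 2 + pad - eps)
      expect_lte(cgm$y + cgm$h / 2, pgm$y + pgm$h / 2 - pad + eps)
    }
  }
})

test_that("sibling leaves do not overlap after layout", {
  for (g in fixture_pool) {
    geom <- layout_pathway(g, fast_opts(seed = 8))
    leaves <- node_ids(g)[vapply(node_ids(g), function(id) {
      length(g$children[[id]]) == 0
    }, logical(1))]
    for (i in seq_along(leaves)) {
      for (j in seq_len(i - 1)) {
        a <- leaves[i]; b <- leaves[j]
        pa <- get_node(g, a)$parent; pb <- get_node(g, b)$parent
        if (identical(pa, pb) || (is.na(pa) && is.na(pb))) {
          expect_equal(overlap_area(geom[[a]], geom[[b]]), 0,
                       info = paste(a, b))
        }
      }
    }
  }
})

test_that("disconnected components do not overlap", {
  g <- pathway_graph()
  for (id in c("A", "B", "X", "Y")) g <- add_node(g, id)
  g <- add_edge(g, "e1", "A", "B")
  g <- add_edge(g, "e2", "X", "Y")
  geom <- layout_pathway(g, fast_opts(seed = 6))
  bbox <- function(ids) {
    b <- geom[ids]
    c(min(vapply(b, function(q) q$x - q$w / 2, numeric(1))),
      max(vapply(b, function(q) q$x + q$w / 2, numeric(1))))
  }
  b1 <- bbox(c("A", "B")); b2 <- bbox(c("X", "Y"))
  expect_true(b1[2] <= b2[1] || b2[2] <= b1[1])
})

test_that("a connected pair settles near the ideal edge length", {
  g <- graph_from_arrows("A->B")
  geom <- layout_pathway(g, layout_options(seed = 1))
  d <- sqrt((geom$A$x - geom$B$x)^2 + (geom$A$y - geom$B$y)^2)
  expect_lt(abs(d - 50) / 50, 0.2)
})

test_that("K3 with equal defaults is close to symmetric", {
  g <- canonical_graphs()$k3
  geom <- layout_pathway(g, layout_options(seed = 2))
  d <- function(a, b) sqrt((geom[[a]]$x - geom[[b]]$x)^2 +
                           (geom[[a]]$y - geom[[b]]$y)^2)
  dists <- c(d("A", "B"), d("B", "C"), d("A", "C"))
  expect_lt((max(dists) - min(dists)) / mean(dists), 0.05)
})

test_that("mean edge length stays within a factor 2 of ideal on trees", {
  g <- pathway_graph()
  set.seed(31)
  ids <- sprintf("t%02d", 1:25)
  for (i in seq_along(ids)) {
    g <- add_node(g, ids[i])
    if (i > 1) {
      g <- add_edge(g, sprintf("e%d", i), ids[sample(i - 1, 1)], ids[i])
    }
  }
  geom <- layout_pathway(g, layout_options(seed = 9, max_iterations = 800))
  lens <- vapply(g$edges, function(e) {
    sqrt((geom[[e$source]]$x - geom[[e$target]]$x)^2 +
         (geom[[e$source]]$y - geom[[e$target]]$y)^2)
  }, numeric(1))
  expect_gt(mean(lens), 50 / 2)
  expect_lt(mean(lens), 50 * 2)
})

test_that("option parsing rejects unknown keys and placement constraints", {
  expect_error(layout_options_from_list(list(fixedNodeConstraint = list())),
               "not supported")
  expect_error(layout_options_from_list(list(bogus = 1)), "unknown layout")
  lo <- layout_options_from_list(list(idealEdgeLength = 80, seed = 4))
  expect_equal(lo$ideal_edge_length, 80)
  expect_error(layout_options(ideal_edge_length = -1))
})
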