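cg <- canonical_graphs()

test_that("compound_bfs matches textbook BFS on flat graphs", {
  for (seed in 1:20) {
    g <- random_flat_graph(n_nodes = sample(3:12, 1), n_edges = sample(3:20, 1),
                           seed = seed)
    src <- sample(node_ids(g), sample(1:2, 1))
    for (dir in c("downstream", "upstream", "both")) {
      k <- sample(c(1, 2, 3, Inf), 1)
      got <- compound_bfs(g, src, dir, k)
      want <- oracle_bfs(g, src, dir, k)
      expect_mapequal(as.list(got), as.list(want))
    }
  }
})

test_that("compound_bfs treats containment as free and saturates closures", {
  nest3 <- cg$nest3
  # member of a complex with an outgoing arc on the complex itself
  d <- compound_bfs(nest3, "m1", "downstream", 1)
  expect_equal(d[["Z"]], 1)          # arc from the complex costs 1
  expect_equal(d[["cx"]], 0)         # parent co-reached
  expect_equal(d[["comp"]], 0)       # grandparent co-reached
  expect_equal(d[["m2"]], 0)         # sibling via parent saturation
  # single isolated node
  g <- add_node(pathway_graph(), "solo")
  expect_equal(compound_bfs(g, "solo", "downstream", 5), c(solo = 0L))
  expect_error(compound_bfs(g, "ghost"), "unknown")
})

test_that("compound queries equal flat queries on the 0-weight reduction", {
  for (seed in 1:10) {
    g <- random_compound_graph(n_leaves = 8, n_compounds = 4,
                               n_edges = 14, seed = seed)
    src <- sample(node_ids(g), 1)
    for (dir in c("downstream", "upstream", "both")) {
      got <- compound_bfs(g, src, dir, Inf)
      want <- oracle_compound_distances(g, src, dir)
      want <- want[is.finite(want)]
      expect_mapequal(as.list(got), as.list(want))
    }
  }
})

test_that("neighborhood collects nodes within k and the traversed arcs", {
  # chain upstream example
  r <- neighborhood(cg$path4, "D", "upstream", 2)
  expect_setequal(r$result_nodes, c("D", "C", "B"))
  expect_setequal(r$result_edges, c("e1", "e2"))  # B->C, C->D
  # star downstream
  r2 <- neighborhood(cg$star4, "S", "downstream", 1)
  expect_setequal(r2$result_nodes, c("S", "L1", "L2", "L3", "L4"))
  expect_length(r2$result_edges, 4)
  # union over sources on disjoint components
  g <- graph_from_arrows(c("A->B", "X->Y"))
  r3 <- neighborhood(g, c("A", "X"), "downstream", 1)
  expect_setequal(r3$result_nodes, c("A", "B", "X", "Y"))
  # monotone in k
  for (seed in 1:5) {
    gg <- random_flat_graph(10, 15, seed)
    src <- sample(node_ids(gg), 1)
    prev <- character(0)
    for (k in 0:4) {
      cur <- neighborhood(gg, src, "downstream", k)$result_nodes
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("common_stream finds nodes reachable from every seed", {
  g <- graph_from_arrows(c("A->X", "B->X"))
  r <- common_stream(g, c("A", "B"), "downstream", 1)
  expect_setequal(r$result_nodes, "X")
  expect_length(r$result_edges, 2)
  expect_equal(unname(r$distances["X"]), 1)
  # roles partition into disjoint seed/result/link
  roles <- r$roles
  expect_setequal(names(roles)[roles == "seed"], c("A", "B"))
  expect_setequal(names(roles)[roles == "result"], "X")

  # k-sensitivity: A->X->Y, B->Y
  g2 <- graph_from_arrows(c("A->X", "X->Y", "B->Y"))
  expect_length(common_stream(g2, c("A", "B"), "downstream", 1)$result_nodes, 0)
  r2 <- common_stream(g2, c("A", "B"), "downstream", 2)
  expect_setequal(r2$result_nodes[r2$roles[r2$result_nodes] == "result"], "Y")
  expect_true("X" %in% names(r2$roles)[r2$roles == "link"])
  expect_equal(unname(r2$distances["Y"]), 2)  # max over sources of min dist

  expect_error(common_stream(g, "A"), "at least 2")
})

test_that("common_stream is contained in each seed's neighborhood", {
  for (seed in 1:8) {
    g <- random_flat_graph(10, 18, seed)
    seeds <- sample(node_ids(g), 2)
    r <- common_stream(g, seeds, "downstream", 3)
    common <- names(r$roles)[r$roles == "result"]
    for (s in seeds) {
      nb <- neighborhood(g, s, "downstream", 3)$result_nodes
      expect_true(all(common %in% nb))
    }
  }
})

test_that("common_stream both-direction is the union of the two runs", {
  g <- graph_from_arrows(c("A->X", "B->X", "R->A", "R->B"))
  r <- common_stream(g, c("A", "B"), "both", 2)
  common <- names(r$roles)[r$roles == "result"]
  expect_setequal(common, c("X", "R"))
})

test_that("paths_between enumerates seed-to-seed links without seed hops", {
  g <- graph_from_arrows(c("A->B"))
  r <- paths_between(g, c("A", "B"), limit_k = 1)
  expect_equal(r$paths, list(c("A", "B")))

  g2 <- graph_from_arrows(c("A->X", "X->B", "A->Y", "Y->B"))
  r2 <- paths_between(g2, c("A", "B"), limit_k = 2)
  expect_length(r2$paths, 2)
  r1 <- paths_between(g2, c("A", "B"), limit_k = 1)
  expect_length(r1$paths, 0)
  expect_setequal(setdiff(r1$result_nodes, character(0)), c("A", "B"))

  # a path through a third seed is excluded
  g3 <- graph_from_arrows(c("A->S", "S->B", "A->Z", "Z->B"))
  r3 <- paths_between(g3, c("A", "B", "S"), limit_k = 2)
  sigs <- path_signature(r3$paths)
  expect_true("A>Z>B" %in% sigs)
  expect_false("A>S>B" %in% sigs)   # S is a seed: only A>S and S>B links
  expect_true(all(c("A>S", "S>B") %in% sigs))

  expect_error(paths_between(g, "A", 2), "at least 2")
})

test_that("paths_between matches exhaustive enumeration on random graphs", {
  for (seed in 1:15) {
    g <- random_flat_graph(sample(5:10, 1), sample(6:16, 1), seed)
    seeds <- sample(node_ids(g), 2)
    k <- sample(2:4, 1)
    got <- path_signature(paths_between(g, seeds, k)$paths)
    want <- c(
      oracle_simple_paths(g, seeds[1], seeds[2], k,
                          forbidden_intermediate = seeds),
      oracle_simple_paths(g, seeds[2], seeds[1], k,
                          forbidden_intermediate = seeds))
    expect_identical(got, path_signature(want))
  }
})

test_that("paths_from_to returns near-shortest paths per pair", {
  worked <- cg$worked_example
  r <- paths_from_to(worked, "s", "t", additional_d = 2)
  lens <- sort(vapply(r$paths, function(p) length(p) - 1L, integer(1)))
  expect_equal(lens, c(3L, 4L, 5L))

  # d = 0: exactly the shortest paths
  r0 <- paths_from_to(worked, "s", "t")
  expect_equal(vapply(r0$paths, length, integer(1)) - 1L, 3L)

  # k caps below the relaxation
  rk <- paths_from_to(worked, "s", "t", limit_k = 4, additional_d = 2)
  expect_equal(sort(vapply(rk$paths, function(p) length(p) - 1L, integer(1))),
               c(3L, 4L))

  # unreachable pair: empty result, no error
  g <- graph_from_arrows("A->B", extra_nodes = "C")
  expect_length(paths_from_to(g, "A", "C")$paths, 0)
})

test_that("paths_from_to matches exhaustive enumeration and is monotone in d", {
  for (seed in 1:15) {
    g <- random_flat_graph(sample(5:10, 1), sample(6:16, 1), seed)
    st <- sample(node_ids(g), 2)
    dist <- oracle_bfs(g, st[1])
    L <- dist[st[2]]
    prev <- 0L
    for (d in 0:2) {
      got <- paths_from_to(g, st[1], st[2], additional_d = d)$paths
      if (is.na(L)) {
        expect_length(got, 0)
      } else {
        want <- oracle_simple_paths(g, st[1], st[2], max_len = L + d)
        want <- Filter(function(p) length(p) - 1 >= L, want)
        expect_identical(path_signature(got), path_signature(want))
        expect_gte(length(got), prev)
        prev <- length(got)
      }
    }
  }
})

test_that("shortest_path picks the lexicographically smallest tie", {
  g <- graph_from_arrows(c("A->B", "B->D", "A->C", "C->D"))
  r <- shortest_path(g, "A", "D")
  expect_equal(r$paths[[1]], c("A", "B", "D"))
  # direct arc
  expect_equal(shortest_path(graph_from_arrows("A->B"), "A", "B")$paths[[1]],
               c("A", "B"))
  # unreachable: empty result, no error
  g2 <- graph_from_arrows("A->B", extra_nodes = "C")
  expect_length(shortest_path(g2, "A", "C")$paths, 0)
  expect_error(shortest_path(g2, "A", "A"), "must differ")

  # cross-check path length against igraph on random graphs
  for (seed in 1:10) {
    g3 <- random_flat_graph(8, 14, seed)
    st <- sample(node_ids(g3), 2)
    r3 <- shortest_path(g3, st[1], st[2])
    ig <- to_igraph(g3)
    suppressWarnings(
      want <- igraph::distances(ig, st[1], st[2], mode = "out"))
    if (is.infinite(want[1, 1])) {
      expect_length(r3$paths, 0)
    } else {
      expect_equal(length(r3$paths[[1]]) - 1, unname(want[1, 1]))
    }
  }
})

test_that("enumerated paths are simple and enumeration terminates on cycles", {
  g <- graph_from_arrows(c("A->B", "B->C", "C->A", "B->D", "D->C"))
  r <- paths_from_to(g, "A", "C", additional_d = 3)
  for (p in r$paths) expect_false(anyDuplicated(p) > 0)
  r2 <- paths_between(g, c("A", "C"), limit_k = 5)
  for (p in r2$paths) expect_false(anyDuplicated(p) > 0)
  # enumeration guard
  expect_error(
    paths_between(g, c("A", "C"), limit_k = 5, max_paths = 1),
    "exceeded")
})

test_that("query results respect the endpoint invariant", {
  for (seed in 1:5) {
    g <- random_compound_graph(8, 3, 12, seed)
    seeds <- sample(node_ids(g), 2)
    for (r in list(neighborhood(g, seeds, "downstream", 2),
                   common_stream(g, seeds, "downstream", 3),
                   paths_between(g, seeds, 3))) {
      allowed <- union(r$result_nodes, r$seed_nodes)
      for (eid in r$result_edges) {
        e <- get_edge(g, eid)
        expect_true(all(c(e$source, e$target) %in% allowed))
      }
    }
  }
})
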