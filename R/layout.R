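#' Layout options
#'
#' Tuning knobs of the compound spring embedder.
#'
#' @param ideal_edge_length Target arc length in px.
#' @param randomize `TRUE` ignores any input coordinates and starts from a
#'   seeded draft; `FALSE` keeps existing coordinates and only places
#'   coordinate-less nodes before refining.
#' @param max_iterations Force-refinement iteration cap.
#' @param convergence_threshold Stop once the total displacement per
#'   iteration falls below this many px.
#' @param gravity_strength Pull of each node toward its parent's (or the
#'   map's) center, per iteration, dimensionless.
#' @param compound_padding Border in px kept between a compound's boundary
#'   and its members.
#' @param seed Integer seed making the layout deterministic.
#' @return A `layout_options` list.
#' @export
layout_options <- function(ideal_edge_length = 50, randomize = TRUE,
                           max_iterations = 2500, convergence_threshold = 1.0,
                           gravity_strength = 0.25, compound_padding = 10,
                           seed = 1L) {
  stopifnot(ideal_edge_length > 0, max_iterations >= 1,
            compound_padding >= 0, gravity_strength >= 0,
            convergence_threshold >= 0)
  structure(list(ideal_edge_length = ideal_edge_length,
                 randomize = isTRUE(randomize),
                 max_iterations = as.integer(max_iterations),
                 convergence_threshold = convergence_threshold,
                 gravity_strength = gravity_strength,
                 compound_padding = compound_padding,
                 seed = as.integer(seed)),
            class = "layout_options")
}

# Parse a layout-options block arriving as a (possibly camelCase) list from
# JSON; unknown keys are rejected, as are fCoSE-style placement constraints.
layout_options_from_list <- function(x) {
  if (is.null(x)) return(layout_options())
  if (inherits(x, "layout_options")) return(x)
  rejected <- c("fixedNodeConstraint", "alignmentConstraint",
                "relativePlacementConstraint")
  hit <- intersect(names(x), rejected)
  if (length(hit)) {
    stop(sprintf("placement constraints are not supported: %s",
                 paste(hit, collapse = ", ")), call. = FALSE)
  }
  key_alias <- c(idealEdgeLength = "ideal_edge_length",
                 maxIterations = "max_iterations",
                 convergenceThreshold = "convergence_threshold",
                 gravityStrength = "gravity_strength",
                 compoundPadding = "compound_padding")
  nm <- names(x)
  nm[nm %in% names(key_alias)] <- key_alias[nm[nm %in% names(key_alias)]]
  names(x) <- nm
  known <- names(formals(layout_options))
  unknown <- setdiff(nm, known)
  if (length(unknown)) {
    stop(sprintf("unknown layout option(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(layout_options, x)
}

# movable particles: leaf nodes and childless compounds
movable_ids <- function(graph) {
  node_ids(graph)[vapply(node_ids(graph), function(id) {
    length(graph$children[[id]]) == 0
  }, logical(1))]
}

leaf_size <- function(graph, id) {
  gm <- graph$nodes[[id]]$geometry
  if (is.null(gm)) c(40, 40) else c(gm$w, gm$h)
}

# Representative movable nodes of an arc endpoint: the endpoint itself if
# movable, otherwise all movable descendants of the compound.
endpoint_reps <- function(graph, id, movable) {
  if (id %in% movable) return(id)
  intersect(descendants(graph, id), movable)
}

#' Draft placement
#'
#' Seeded random placement inside a sqrt(n)-scaled square -- members jittered
#' around a per-containment-tree cluster center -- followed by one BFS-tree
#' pass over the arcs that rings newly discovered neighbors around their
#' discoverer at the ideal edge length. With `randomize = FALSE`, nodes that
#' already have coordinates keep them and only coordinate-less nodes are
#' placed. Leaves without sizes get the 40x40 px default.
#'
#' @param graph A `pathway_graph`.
#' @param options A [layout_options()].
#' @return Named list `id -> list(x, y, w, h)` covering every node.
#' @export
draft_placement <- function(graph, options = layout_options()) {
  ids <- node_ids(graph)
  if (!length(ids)) return(stats::setNames(list(), character(0)))
  movable <- movable_ids(graph)
  L <- options$ideal_edge_length
  side <- max(2, sqrt(length(movable))) * L
  with_private_seed(options$seed, {
    pos <- matrix(0, nrow = length(movable), ncol = 2,
                  dimnames = list(movable, c("x", "y")))
    # cluster centers per containment root keep siblings together
    root_of <- vapply(movable, function(id) {
      anc <- ancestors(graph, id)
      if (length(anc)) anc[[length(anc)]] else id
    }, character(1))
    centers <- unique(root_of)
    cpos <- matrix(stats::runif(2 * length(centers), 0, side),
                   ncol = 2, dimnames = list(centers, NULL))
    jitter_scale <- L
    for (i in seq_along(movable)) {
      id <- movable[i]
      keep <- !options$randomize && !is.null(graph$nodes[[id]]$geometry)
      if (keep) {
        gm <- graph$nodes[[id]]$geometry
        pos[i, ] <- c(gm$x, gm$y)
      } else {
        pos[i, ] <- cpos[root_of[[id]], ] +
          stats::runif(2, -jitter_scale, jitter_scale)
      }
    }
    # one BFS-tree pass over arcs: ring unvisited neighbors around parents
    if (options$randomize && length(graph$edges)) {
      nbrs <- stats::setNames(vector("list", length(movable)), movable)
      for (e in graph$edges) {
        for (u in endpoint_reps(graph, e$source, movable)) {
          for (v in endpoint_reps(graph, e$target, movable)) {
            if (u != v) {
              nbrs[[u]] <- c(nbrs[[u]], v)
              nbrs[[v]] <- c(nbrs[[v]], u)
            }
          }
        }
      }
      visited <- stats::setNames(rep(FALSE, length(movable)), movable)
      for (start in movable) {
        if (visited[[start]]) next
        visited[start] <- TRUE
        queue <- start
        while (length(queue)) {
          cur <- queue[[1]]; queue <- queue[-1]
          fresh <- unique(nbrs[[cur]])
          fresh <- fresh[!visited[fresh]]
          if (length(fresh)) {
            # independent random angles: evenly spaced rings put neighbor
            # pairs diametrically opposite, a collinear saddle the forces
            # cannot escape
            ang <- 2 * pi * (seq_along(fresh) - 1) / length(fresh) +
              stats::runif(length(fresh), 0, 2 * pi / length(fresh))
            pos[fresh, 1] <- pos[cur, 1] + L * cos(ang)
            pos[fresh, 2] <- pos[cur, 2] + L * sin(ang)
            visited[fresh] <- TRUE
            queue <- c(queue, fresh)
          }
        }
      }
    }
    geometry_from_positions(graph, pos, options$compound_padding)
  })
}

# Assemble a full geometry map from movable-node positions: leaves get their
# (possibly default) sizes, compounds the bounding box of their members plus
# padding, computed bottom-up.
geometry_from_positions <- function(graph, pos, padding) {
  geom <- list()
  movable <- rownames(pos)
  for (id in movable) {
    sz <- leaf_size(graph, id)
    geom[[id]] <- list(x = pos[id, 1], y = pos[id, 2], w = sz[1], h = sz[2])
  }
  comps <- setdiff(node_ids(graph), movable)
  if (length(comps)) {
    depth <- vapply(comps, function(id) length(ancestors(graph, id)),
                    numeric(1))
    for (id in comps[order(-depth)]) {
      kids <- graph$children[[id]]
      boxes <- geom[kids]
      x1 <- min(vapply(boxes, function(b) b$x - b$w / 2, numeric(1))) - padding
      y1 <- min(vapply(boxes, function(b) b$y - b$h / 2, numeric(1))) - padding
      x2 <- max(vapply(boxes, function(b) b$x + b$w / 2, numeric(1))) + padding
      y2 <- max(vapply(boxes, function(b) b$y + b$h / 2, numeric(1))) + padding
      geom[[id]] <- list(x = (x1 + x2) / 2, y = (y1 + y2) / 2,
                         w = x2 - x1, h = y2 - y1)
    }
  }
  geom[node_ids(graph)]
}

#' Force-directed refinement
#'
#' Iterative compound spring embedder: every arc pulls its endpoints toward
#' the ideal edge length, all movable node pairs repel with a clipped
#' inverse-square force (plus a hard push when their rectangles overlap),
#' and gravity draws members toward their parent compound's center.
#' Compound bounds are recomputed from their members every iteration, so
#' containment (member rectangle inside parent minus padding) holds by
#' construction. Displacement per iteration is capped, the cap cooling
#' linearly from the ideal edge length down to 1 px; iteration stops at
#' `max_iterations` or when total displacement falls below the convergence
#' threshold. A deterministic post-pass separates overlapping sibling leaves
#' and packs disconnected components so they do not overlap.
#'
#' @param graph A `pathway_graph`.
#' @param geometry Draft geometry map covering all nodes.
#' @param options A [layout_options()].
#' @return Refined geometry map.
#' @export
refine_layout <- function(graph, geometry, options = layout_options()) {
  movable <- movable_ids(graph)
  n <- length(movable)
  if (n == 0) return(geometry)
  L <- options$ideal_edge_length
  px <- vapply(movable, function(id) geometry[[id]]$x, numeric(1))
  py <- vapply(movable, function(id) geometry[[id]]$y, numeric(1))
  wv <- vapply(movable, function(id) geometry[[id]]$w, numeric(1))
  hv <- vapply(movable, function(id) geometry[[id]]$h, numeric(1))
  idx <- stats::setNames(seq_len(n), movable)

  # spring terms: arcs mapped to movable representatives, weight split over
  # compound members
  si <- integer(0); sj <- integer(0); sw <- numeric(0)
  for (e in graph$edges) {
    reps_s <- endpoint_reps(graph, e$source, movable)
    reps_t <- endpoint_reps(graph, e$target, movable)
    for (u in reps_s) {
      for (v in reps_t) {
        if (u != v) {
          si <- c(si, idx[[u]]); sj <- c(sj, idx[[v]])
          sw <- c(sw, 1 / (length(reps_s) * length(reps_t)))
        }
      }
    }
  }
  parent_idx <- lapply(movable, function(id) {
    p <- graph$nodes[[id]]$parent
    if (is.na(p)) integer(0) else idx[intersect(descendants(graph, p), movable)]
  })

  spring_k <- 0.3
  rep_c <- 0.25 * L^2
  step_total <- Inf
  for (it in seq_len(options$max_iterations)) {
    cap <- max(1, L * (1 - (it - 1) / options$max_iterations))
    fx <- numeric(n); fy <- numeric(n)
    # pairwise repulsion (vectorized)
    dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf
    d2 <- pmax(d2, 1)
    fr <- rep_c / d2
    dd <- sqrt(d2)
    # deterministic nudge for coincident points
    coincident <- d2 <= 1.0000001 & row(d2) != col(d2)
    if (any(coincident)) {
      ang <- (row(d2) * 7 + col(d2) * 13) %% 17 / 17 * 2 * pi
      dx[coincident] <- cos(ang[coincident])
      dy[coincident] <- sin(ang[coincident])
      dd[coincident] <- 1
    }
    fx <- rowSums(fr * dx / dd)
    fy <- rowSums(fr * dy / dd)
    # springs
    if (length(si)) {
      ex <- px[sj] - px[si]; ey <- py[sj] - py[si]
      ed <- pmax(sqrt(ex * ex + ey * ey), 1e-6)
      f <- spring_k * (ed - L) * sw
      fxs <- f * ex / ed; fys <- f * ey / ed
      for (k in seq_along(si)) {
        fx[si[k]] <- fx[si[k]] + fxs[k]; fy[si[k]] <- fy[si[k]] + fys[k]
        fx[sj[k]] <- fx[sj[k]] - fxs[k]; fy[sj[k]] <- fy[sj[k]] - fys[k]
      }
    }
    # gravity toward sibling-group center (parent compound center)
    for (i in seq_len(n)) {
      grp <- parent_idx[[i]]
      if (length(grp) > 1) {
        fx[i] <- fx[i] + options$gravity_strength * (mean(px[grp]) - px[i])
        fy[i] <- fy[i] + options$gravity_strength * (mean(py[grp]) - py[i])
      }
    }
    if (any(!is.finite(fx)) || any(!is.finite(fy))) {
      stop("layout forces diverged (non-finite displacement)", call. = FALSE)
    }
    mag <- sqrt(fx * fx + fy * fy)
    scale <- ifelse(mag > cap, cap / mag, 1)
    px <- px + fx * scale
    py <- py + fy * scale
    step_total <- sum(mag * scale)
    if (step_total < options$convergence_threshold) break
  }

  pos <- cbind(x = px, y = py)
  rownames(pos) <- movable
  pos <- separate_sibling_overlaps(graph, pos, wv, hv)
  geom <- geometry_from_positions(graph, pos, options$compound_padding)
  pack_components(graph, geom, options)
}

# Deterministic push-apart of overlapping leaves that share a parent.
separate_sibling_overlaps <- function(graph, pos, wv, hv, max_pass = 300L) {
  ids <- rownames(pos)
  n <- length(ids)
  if (n < 2) return(pos)
  parent <- vapply(ids, function(id) {
    p <- graph$nodes[[id]]$parent
    if (is.na(p)) "" else p
  }, character(1))
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (parent[i] != parent[j]) next
        ox <- (wv[i] + wv[j]) / 2 - abs(pos[i, 1] - pos[j, 1])
        oy <- (hv[i] + hv[j]) / 2 - abs(pos[i, 2] - pos[j, 2])
        if (ox > 0 && oy > 0) {
          moved <- TRUE
          if (ox < oy) {
            sgn <- if (pos[i, 1] <= pos[j, 1]) 1 else -1
            pos[i, 1] <- pos[i, 1] - sgn * (ox / 2 + 1)
            pos[j, 1] <- pos[j, 1] + sgn * (ox / 2 + 1)
          } else {
            sgn <- if (pos[i, 2] <= pos[j, 2]) 1 else -1
            pos[i, 2] <- pos[i, 2] - sgn * (oy / 2 + 1)
            pos[j, 2] <- pos[j, 2] + sgn * (oy / 2 + 1)
          }
        }
      }
    }
    if (!moved) break
  }
  pos
}

# Shift whole connected components (arcs + containment both connect) so
# their bounding boxes sit side by side with a margin.
pack_components <- function(graph, geom, options) {
  ids <- node_ids(graph)
  if (length(ids) < 2) return(geom)
  # simple union-find over integer roots
  root <- seq_along(ids); names(root) <- ids
  findr <- function(i) {
    while (root[[i]] != i) i <- root[[i]]
    i
  }
  unite <- function(a, b) {
    ra <- findr(which(ids == a)); rb <- findr(which(ids == b))
    if (ra != rb) root[[max(ra, rb)]] <<- min(ra, rb)
  }
  for (e in graph$edges) unite(e$source, e$target)
  for (nd in graph$nodes) if (!is.na(nd$parent)) unite(nd$id, nd$parent)
  groups <- split(ids, vapply(seq_along(ids), findr, integer(1)))
  if (length(groups) < 2) return(geom)
  margin <- 2 * options$compound_padding + 20
  cursor_x <- 0
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    boxes <- geom[members]
    x1 <- min(vapply(boxes, function(b) b$x - b$w / 2, numeric(1)))
    y1 <- min(vapply(boxes, function(b) b$y - b$h / 2, numeric(1)))
    x2 <- max(vapply(boxes, function(b) b$x + b$w / 2, numeric(1)))
    shift_x <- cursor_x - x1
    shift_y <- -y1
    for (m in members) {
      geom[[m]]$x <- geom[[m]]$x + shift_x
      geom[[m]]$y <- geom[[m]]$y + shift_y
    }
    cursor_x <- cursor_x + (x2 - x1) + margin
  }
  geom
}

#' Automatic compound layout
#'
#' [draft_placement()] followed by [refine_layout()]; the result assigns
#' finite geometry to every node, keeps members inside their compounds and
#' is deterministic for a fixed `(graph, options, seed)`.
#'
#' @param graph A `pathway_graph`.
#' @param options A [layout_options()].
#' @return Named geometry map `id -> list(x, y, w, h)`.
#' @export
layout_pathway <- function(graph, options = layout_options()) {
  draft <- draft_placement(graph, options)
  if (!length(draft)) return(draft)
  refine_layout(graph, draft, options)
}
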