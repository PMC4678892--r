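#' Canonical orientation of an edge-path
#'
#' A path and its reversal describe the same filament; candidate sets store
#' one canonical representative. Open paths keep the lexicographically
#' smaller of the node sequence and its reversal. Closed loops are first
#' rotated to start at their minimal node id, then the lexicographically
#' smaller direction is kept.
#'
#' @param path integer vector of node ids (closed path: first == last)
#' @return the canonical node-id vector
#' @export
canonicalize_path <- function(path) {
  path <- as.integer(path)
  if (length(path) >= 3 && path[1] == path[length(path)]) {
    cyc <- path[-length(path)]
    k <- length(cyc)
    s <- which(cyc == min(cyc))[1]
    fwd <- cyc[((seq_len(k) + s - 2L) %% k) + 1L]
    rev_cyc <- rev(cyc)
    s2 <- which(rev_cyc == min(rev_cyc))[1]
    bwd <- rev_cyc[((seq_len(k) + s2 - 2L) %% k) + 1L]
    best <- if (lex_less(bwd, fwd)) bwd else fwd
    return(c(best, best[1]))
  }
  rp <- rev(path)
  if (lex_less(rp, path)) rp else path
}

# TRUE if integer vector a < b lexicographically (equal-length assumed)
lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

path_key <- function(path) paste(path, collapse = ",")

new_candidate_paths <- function(paths, provenance) {
  structure(
    list(paths = paths, provenance = provenance, includes_singletons = TRUE),
    class = "candidate_paths"
  )
}

#' @export
print.candidate_paths <- function(x, ...) {
  cat(sprintf("<candidate_paths> %d paths (%s)\n",
              length(x$paths), x$provenance))
  invisible(x)
}

# all single-edge paths, canonical (from < to already holds)
singleton_paths <- function(graph) {
  lapply(seq_len(n_edges(graph)), function(i) {
    c(graph$edges$from[i], graph$edges$to[i])
  })
}

# neighbour table: for each node row, integer vector of adjacent node rows
# plus the connecting edge index
adjacency_table <- function(graph) {
  n <- n_nodes(graph)
  fr <- node_row(graph, graph$edges$from)
  to <- node_row(graph, graph$edges$to)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nb = integer(0), eid = integer(0))
  for (e in seq_len(n_edges(graph))) {
    adj[[fr[e]]]$nb <- c(adj[[fr[e]]]$nb, to[e])
    adj[[fr[e]]]$eid <- c(adj[[fr[e]]]$eid, e)
    adj[[to[e]]]$nb <- c(adj[[to[e]]]$nb, fr[e])
    adj[[to[e]]]$eid <- c(adj[[to[e]]]$eid, e)
  }
  adj
}

#' Sample candidate paths by angle-constrained breadth-first search
#'
#' Enumerates every edge-path (including closed loops) whose maximal
#' deflection angle stays strictly below `angle_max_deg`, by breadth-wise
#' extension of partial paths from every starting edge: an extension whose
#' newest deflection reaches the threshold is pruned, which keeps the
#' enumeration tractable on filamentous graphs where node degrees are small
#' and crossings meet at wide angles. A partial path may close into a loop
#' only at its own start node; on closure the deflection across the seam
#' (last segment against first segment) is also checked, so loop filaments
#' cannot bend arbitrarily at the junction. Single-edge paths are always
#' included, which guarantees that the cover problem is feasible.
#'
#' @param graph a [filament_graph()] with node positions
#' @param angle_max_deg strict upper bound on deflection angles (degrees)
#' @param max_paths safety cap; enumeration beyond this count raises a
#'   resource error rather than silently truncating.
#' @return object of class `candidate_paths`: deduplicated canonical paths,
#'   provenance `"BFS"`.
#' @export
sample_paths_bfs <- function(graph, angle_max_deg = 60, max_paths = 1e6) {
  stopifnot(angle_max_deg > 0, angle_max_deg < 180)
  cols <- c("x", "y", if (graph$dim == 3L) "z")
  pos <- as.matrix(graph$nodes[, cols, drop = FALSE])
  ids <- graph$nodes$id
  adj <- adjacency_table(graph)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 256L)
  n_out <- 0L
  add_path <- function(p_rows) {
    p <- canonicalize_path(ids[p_rows])
    k <- path_key(p)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      n_out <<- n_out + 1L
      if (n_out > max_paths) {
        stop(sprintf("resource error: more than %g admissible paths; raise `max_paths` or tighten the angle threshold",
                     max_paths), call. = FALSE)
      }
      out[[n_out]] <<- p
    }
  }
  # cosine threshold: deflection < angle_max  <=>  cos(deflection) > cos(angle_max)
  cos_min <- cos(angle_max_deg * pi / 180)
  deflect_ok <- function(d1, d2) {
    s <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
    s > cos_min + 1e-12
  }

  fr <- node_row(graph, graph$edges$from)
  to <- node_row(graph, graph$edges$to)
  # frontier entries: list(rows, eids, first_dir, last_dir)
  frontier <- vector("list", 2L * n_edges(graph))
  fi <- 0L
  for (e in seq_len(n_edges(graph))) {
    add_path(c(fr[e], to[e]))
    for (ori in 1:2) {
      a <- if (ori == 1) fr[e] else to[e]
      b <- if (ori == 1) to[e] else fr[e]
      d <- pos[b, ] - pos[a, ]
      fi <- fi + 1L
      frontier[[fi]] <- list(rows = c(a, b), eids = e, first = d, last = d)
    }
  }
  frontier <- frontier[seq_len(fi)]

  while (length(frontier) > 0) {
    nxt <- vector("list", 0L)
    for (st in frontier) {
      tail_row <- st$rows[length(st$rows)]
      nbs <- adj[[tail_row]]
      for (j in seq_along(nbs$nb)) {
        e2 <- nbs$eid[j]
        if (e2 %in% st$eids) next
        x <- nbs$nb[j]
        d2 <- pos[x, ] - pos[tail_row, ]
        if (!deflect_ok(st$last, d2)) next
        if (x == st$rows[1]) {
          # closure: also check the seam deflection
          if (deflect_ok(d2, st$first)) add_path(c(st$rows, x))
          next
        }
        rows2 <- c(st$rows, x)
        add_path(rows2)
        nxt[[length(nxt) + 1L]] <- list(rows = rows2,
                                        eids = c(st$eids, e2),
                                        first = st$first, last = d2)
      }
    }
    frontier <- nxt
  }
  new_candidate_paths(out[seq_len(n_out)], "BFS")
}

#' Sample candidate paths from random minimal spanning trees
#'
#' Repeats `n_trees` times: assign every edge an i.i.d. uniform(0,1)
#' auxiliary weight, compute the minimum spanning tree (per connected
#' component) with respect to those weights, and add the unique tree path
#' between every node pair to the candidate set. Because trees are loopless,
#' no candidate contains a full cycle, which is why loop filaments are
#' over-segmented under this sampler. Single-edge paths are always included.
#'
#' @param graph a [filament_graph()]
#' @param n_trees number of tree repetitions (default 100)
#' @param seed integer seed; the repetitions consume one seeded generator
#'   sequentially, so a fixed seed reproduces the candidate set exactly.
#' @return object of class `candidate_paths`, provenance `"RMST"`.
#' @export
sample_paths_rmst <- function(graph, n_trees = 100L, seed = NULL) {
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(graph)
  ids <- graph$nodes$id
  E <- n_edges(graph)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  add_path <- function(p) {
    p <- canonicalize_path(p)
    k <- path_key(p)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      out[[length(out) + 1L]] <<- p
    }
  }
  for (p in singleton_paths(graph)) add_path(p)
  nv <- n_nodes(graph)
  for (t in seq_len(n_trees)) {
    aux <- stats::runif(E)
    tree <- igraph::mst(ig, weights = aux)
    for (v in seq_len(nv - 1L)) {
      sp <- suppressWarnings(
        igraph::shortest_paths(tree, from = v, to = (v + 1L):nv,
                               weights = NA, output = "vpath")$vpath
      )
      for (vp in sp) {
        if (length(vp) >= 2) add_path(ids[as.integer(vp)])
      }
    }
  }
  new_candidate_paths(out, "RMST")
}

#' Sample candidate paths according to cover options
#'
#' @param graph a [filament_graph()]
#' @param options a [cover_options()]
#' @return object of class `candidate_paths`
#' @export
sample_paths <- function(graph, options = cover_options()) {
  switch(options$sampling,
    bfs = sample_paths_bfs(graph, angle_max_deg = options$angle_max_deg,
                           max_paths = options$max_paths),
    rmst = sample_paths_rmst(graph, n_trees = options$n_trees,
                             seed = options$seed)
  )
}
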