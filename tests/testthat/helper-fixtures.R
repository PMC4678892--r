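# Fixture builders and independent oracles shared across tests. Everything
# is generated in code; no data files.

# straight chain of n nodes on the x-axis with given edge weights
chain_graph <- function(weights, y = 0) {
  n <- length(weights) + 1L
  filament_graph(
    nodes = data.frame(id = seq_len(n) - 1L, x = seq_len(n) - 1, y = y),
    edges = data.frame(from = 0:(n - 2L), to = 1:(n - 1L), weight = weights)
  )
}

# right-angle L: (0,0)-(1,0)-(1,1)
l_graph <- function(weights = c(0.5, 0.5)) {
  filament_graph(
    nodes = data.frame(id = 0:2, x = c(0, 1, 1), y = c(0, 0, 1)),
    edges = data.frame(from = c(0, 1), to = c(1, 2), weight = weights)
  )
}

# X-crossing of two straight 2-edge filaments through a centre node 2:
# horizontal 0-2-1, vertical 3-2-4
x_graph <- function(w_horizontal = 0.8, w_vertical = 0.3) {
  filament_graph(
    nodes = data.frame(id = 0:4, x = c(-1, 1, 0, 0, 0), y = c(0, 0, 0, -1, 1)),
    edges = data.frame(from = c(0, 2, 3, 2), to = c(2, 1, 2, 4),
                       weight = c(w_horizontal, w_horizontal,
                                  w_vertical, w_vertical))
  )
}

# regular k-gon loop (deflections 360/k degrees)
polygon_graph <- function(k = 8, weight = 0.5, r = 1) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  filament_graph(
    nodes = data.frame(id = seq_len(k) - 1L, x = r * cos(th), y = r * sin(th)),
    edges = data.frame(from = seq_len(k) - 1L,
                       to = c(seq_len(k - 1L), 0L),
                       weight = weight)
  )
}

# random small geometric graph: spanning tree over random points plus extra
# edges, at most max_edges edges, random weights
random_tiny_graph <- function(seed, n_nodes = 5L, max_edges = 8L) {
  set.seed(seed)
  n <- n_nodes
  pos <- matrix(stats::runif(2 * n, 0, 10), ncol = 2)
  from <- integer(0); to <- integer(0)
  for (v in 2:n) { # random spanning tree
    u <- sample(v - 1L, 1)
    from <- c(from, u - 1L); to <- c(to, v - 1L)
  }
  extra <- max_edges - length(from)
  tries <- 0L
  while (extra > 0 && tries < 50) {
    tries <- tries + 1L
    uv <- sort(sample(n, 2) - 1L)
    if (!any(from == uv[1] & to == uv[2])) {
      from <- c(from, uv[1]); to <- c(to, uv[2])
      extra <- extra - 1L
    }
  }
  filament_graph(
    nodes = data.frame(id = seq_len(n) - 1L, x = pos[, 1], y = pos[, 2]),
    edges = data.frame(from = from, to = to,
                       weight = stats::runif(length(from), 0.1, 1))
  )
}

# candidate set of at most max_paths paths: all singletons plus random
# longer admissible paths
tiny_candidates <- function(graph, seed, max_paths = 15L) {
  all_paths <- sample_paths_bfs(graph, angle_max_deg = 175,
                                max_paths = 1e5)$paths
  lens <- vapply(all_paths, length, integer(1))
  singles <- all_paths[lens == 2L]
  longer <- all_paths[lens > 2L]
  set.seed(seed + 1L)
  room <- max_paths - length(singles)
  if (length(longer) > room) longer <- sample(longer, max(room, 0L))
  structure(list(paths = c(singles, longer), provenance = "BFS",
                 includes_singletons = TRUE),
            class = "candidate_paths")
}

# exhaustive oracle: enumerate all subsets of candidate paths, return the
# optimal total and average objective over feasible covers
.subset_cache <- new.env(parent = emptyenv())
subset_matrix <- function(np) {
  key <- as.character(np)
  m <- .subset_cache[[key]]
  if (is.null(m)) {
    s <- seq_len(2^np - 1L)
    m <- vapply(seq_len(np), function(j) bitwAnd(s, 2^(j - 1L)) > 0,
                logical(length(s)))
    .subset_cache[[key]] <- m
  }
  m
}

brute_force_optimum <- function(program) {
  np <- length(program$costs)
  stopifnot(np <= 16)
  S <- subset_matrix(np)
  inc <- vapply(seq_len(program$n_edges), function(e) {
    vapply(program$path_edges, function(pe) e %in% pe, logical(1))
  }, logical(np)) # np x E
  cnt <- S %*% inc
  feas <- if (program$exact) rowSums(cnt == 1) == program$n_edges
          else rowSums(cnt >= 1) == program$n_edges
  tot <- as.numeric(S %*% program$costs)
  sizes <- rowSums(S)
  list(total = min(tot[feas]), average = min(tot[feas] / sizes[feas]))
}

# independent classical Rand/Jaccard oracle: plain double loop over all
# unordered edge pairs, intersection rule for overlap membership
classical_indices <- function(labels_a, labels_b) {
  E <- length(labels_a)
  ss <- sd <- ds <- dd <- 0L
  for (i in seq_len(E - 1L)) {
    for (j in (i + 1L):E) {
      sa <- length(intersect(labels_a[[i]], labels_a[[j]])) > 0
      sb <- length(intersect(labels_b[[i]], labels_b[[j]])) > 0
      if (sa && sb) ss <- ss + 1L
      else if (sa && !sb) sd <- sd + 1L
      else if (!sa && sb) ds <- ds + 1L
      else dd <- dd + 1L
    }
  }
  list(RI = (ss + dd) / (ss + sd + ds + dd),
       JI = if (ss + sd + ds == 0) NaN else ss / (ss + sd + ds))
}

# random (possibly overlapping) labelling of a graph's edges
random_labels <- function(graph, seed, k = 3L, overlap_prob = 0.3) {
  set.seed(seed)
  structure(lapply(seq_len(nrow(graph$edges)), function(e) {
    base <- sample.int(k, 1)
    if (stats::runif(1) < overlap_prob) {
      unique(c(base, sample.int(k, 1)))
    } else base
  }), class = "edge_cover_labels")
}
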