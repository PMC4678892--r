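#' Topological distance between two edges
#'
#' The distance between edges `e` and `f` is the minimum, over their four
#' endpoint pairs, of the shortest-path length (in edges) between the
#' endpoints. Two edges sharing a node are at distance 0. By convention,
#' edges are "separated by at most d nodes" iff their distance is at most
#' `d - 1`, so the distance bound `d = 1` selects exactly the pairs of
#' adjacent edges. This numbering convention matters: it silently changes
#' every structure-aware index value, so it is fixed here once.
#'
#' @param graph a [filament_graph()]
#' @param e,f edge indices (rows of `graph$edges`)
#' @return non-negative integer, or `Inf` for a disconnected pair
#' @export
edge_distance <- function(graph, e, f) {
  E <- n_edges(graph)
  stopifnot(e >= 1, e <= E, f >= 1, f <= E)
  edge_distance_matrix(graph)[e, f]
}

# E x E matrix of pairwise edge distances (min over endpoint pairs)
edge_distance_matrix <- function(graph) {
  ig <- as_igraph(graph)
  nd <- igraph::distances(ig, weights = NA)
  fr <- node_row(graph, graph$edges$from)
  to <- node_row(graph, graph$edges$to)
  pmin(nd[fr, fr, drop = FALSE], nd[fr, to, drop = FALSE],
       nd[to, fr, drop = FALSE], nd[to, to, drop = FALSE])
}

as_edge_labels <- function(x, graph) {
  if (inherits(x, "edge_cover_labels")) return(x)
  if (inherits(x, "filament_cover")) return(edge_cover_labels(x, graph))
  if (is.list(x)) return(structure(lapply(x, as.integer),
                                   class = "edge_cover_labels"))
  stop("expected a filament_cover or edge_cover_labels", call. = FALSE)
}

# E x F logical incidence of an edge labelling
label_incidence <- function(labels) {
  ids <- sort(unique(unlist(labels)))
  m <- matrix(FALSE, nrow = length(labels), ncol = length(ids))
  for (e in seq_along(labels)) {
    m[e, match(labels[[e]], ids)] <- TRUE
  }
  m
}

#' Contingency counts of two edge labellings
#'
#' Counts unordered pairs of distinct edges, restricted to pairs whose
#' topological distance is at most `d - 1` (all pairs for `d = Inf`),
#' classified by whether the pair lies in a common filament in each
#' labelling. For potentially overlapping covers, two edges count as being
#' in the "same" set when their membership sets intersect — the minimal
#' consistent extension of the partition case.
#'
#' @param A,B [filament_cover()] or `edge_cover_labels` objects over the
#'   same graph
#' @param graph a [filament_graph()]
#' @param d distance bound (positive integer or `Inf`)
#' @return object of class `contingency_counts`: counts `ss`, `sd`, `ds`,
#'   `dd` (same/different in A then B) plus the bound `d`.
#' @export
contingency_counts <- function(A, B, graph, d = 1) {
  A <- as_edge_labels(A, graph)
  B <- as_edge_labels(B, graph)
  E <- n_edges(graph)
  if (length(A) != E || length(B) != E) {
    stop("consistency error: labellings do not match the graph's edge set",
         call. = FALSE)
  }
  stopifnot(length(d) == 1, d >= 1)
  if (is.finite(d)) {
    admissible <- edge_distance_matrix(graph) <= (d - 1)
  } else {
    admissible <- matrix(TRUE, E, E)
  }
  admissible[lower.tri(admissible, diag = TRUE)] <- FALSE
  MA <- label_incidence(A)
  MB <- label_incidence(B)
  same_a <- tcrossprod(MA) > 0
  same_b <- tcrossprod(MB) > 0
  structure(
    list(ss = sum(admissible & same_a & same_b),
         sd = sum(admissible & same_a & !same_b),
         ds = sum(admissible & !same_a & same_b),
         dd = sum(admissible & !same_a & !same_b),
         d = d),
    class = "contingency_counts"
  )
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("<contingency_counts> d = %s: ss %d, sd %d, ds %d, dd %d\n",
              format(x$d), x$ss, x$sd, x$ds, x$dd))
  invisible(x)
}

#' Rand index from contingency counts
#'
#' `RI = (ss + dd) / (ss + sd + ds + dd)`. With counts restricted to edge
#' pairs at distance bound `d` this is the structure-aware index; at
#' `d = Inf` it is the classical Rand index.
#'
#' @param h a `contingency_counts` object
#' @return value in `[0, 1]`
#' @export
rand_index <- function(h) {
  tot <- h$ss + h$sd + h$ds + h$dd
  if (tot == 0) {
    stop("undefined: no admissible edge pairs at this distance bound",
         call. = FALSE)
  }
  (h$ss + h$dd) / tot
}

#' Jaccard index from contingency counts
#'
#' `JI = ss / (ss + sd + ds)`; at `d = 1` the structure-aware index over
#' adjacent edge pairs only, at `d = Inf` the classical Jaccard index.
#'
#' @inheritParams rand_index
#' @return value in `[0, 1]` (`NaN` when no pair is co-assigned in either
#'   labelling)
#' @export
jaccard_index <- function(h) {
  tot <- h$ss + h$sd + h$ds + h$dd
  if (tot == 0) {
    stop("undefined: no admissible edge pairs at this distance bound",
         call. = FALSE)
  }
  denom <- h$ss + h$sd + h$ds
  if (denom == 0) return(NaN)
  h$ss / denom
}

#' Variation of information between two exact covers
#'
#' `VI = H(A) + H(B) - 2 I(A; B)` with probabilities given by filament
#' edge counts over the common edge set, in natural-log units (the
#' convention of the clustering-comparison literature). VI is only defined
#' for partitions: any overlapping membership raises a domain error.
#'
#' @inheritParams contingency_counts
#' @return non-negative numeric; 0 iff the labellings coincide up to
#'   relabelling
#' @export
variation_of_information <- function(A, B, graph) {
  A <- as_edge_labels(A, graph)
  B <- as_edge_labels(B, graph)
  if (!is_exact_labelling(A) || !is_exact_labelling(B)) {
    stop("domain error: variation of information is not well-defined for overlapping partitions",
         call. = FALSE)
  }
  a <- unlist(A)
  b <- unlist(B)
  E <- length(a)
  tab <- table(a, b)
  p <- tab / E
  pa <- rowSums(p)
  pb <- colSums(p)
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  mi <- 0
  nz <- which(p > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1]; j <- nz[k, 2]
    mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  max(0, ent(pa) + ent(pb) - 2 * mi)
}

#' Match filament identities between two covers
#'
#' Solves a rectangular linear assignment problem (Hungarian algorithm)
#' maximising the total number of edges shared by matched filament pairs,
#' which is how automated covers are aligned with reference assignments
#' before visual or per-filament comparison. Filaments left unmatched (or
#' matched with zero shared edges) keep fresh identities.
#'
#' @param A,B [filament_cover()] objects over `graph`
#' @param graph a [filament_graph()]
#' @return data.frame with columns `a_id`, `b_id` (0-based ids; `b_id` NA
#'   for unmatched), `shared` (edge count); attribute `total_shared` holds
#'   the assignment value.
#' @export
match_filaments <- function(A, B, graph) {
  ea <- lapply(A$paths, function(p) unique(path_edge_ids(graph, p)))
  eb <- lapply(B$paths, function(p) unique(path_edge_ids(graph, p)))
  na <- length(ea)
  nb <- length(eb)
  shared <- matrix(0L, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      shared[i, j] <- length(intersect(ea[[i]], eb[[j]]))
    }
  }
  flip <- na > nb
  m <- if (flip) t(shared) else shared
  sol <- clue::solve_LSAP(m, maximum = TRUE)
  pairs <- cbind(seq_along(sol), as.integer(sol))
  if (flip) pairs <- pairs[, 2:1, drop = FALSE]
  b_of_a <- rep(NA_integer_, na)
  b_of_a[pairs[, 1]] <- pairs[, 2]
  sh <- integer(na)
  matched <- which(!is.na(b_of_a))
  sh[matched] <- shared[cbind(matched, b_of_a[matched])]
  b_of_a[sh == 0L] <- NA_integer_
  out <- data.frame(a_id = seq_len(na) - 1L,
                    b_id = b_of_a - 1L,
                    shared = as.integer(sh))
  attr(out, "total_shared") <- sum(sh)
  out
}

#' Similarity table between two covers
#'
#' Convenience wrapper computing the structure-aware Rand and Jaccard
#' indices for each requested distance bound, plus the variation of
#' information when both covers are exact.
#'
#' @inheritParams contingency_counts
#' @param d_list distance bounds (integers and/or `Inf`)
#' @return data.frame with columns `d`, `RI`, `JI`; attribute `VI` (NA when
#'   undefined due to overlaps).
#' @export
compare_covers <- function(A, B, graph, d_list = c(1, Inf)) {
  A <- as_edge_labels(A, graph)
  B <- as_edge_labels(B, graph)
  rows <- lapply(d_list, function(d) {
    h <- contingency_counts(A, B, graph, d = d)
    data.frame(d = d, RI = rand_index(h), JI = jaccard_index(h))
  })
  out <- do.call(rbind, rows)
  vi <- if (is_exact_labelling(A) && is_exact_labelling(B)) {
    variation_of_information(A, B, graph)
  } else NA_real_
  attr(out, "VI") <- vi
  out
}

# structure-aware Jaccard agreement at d = 1 between a cover and reference
# labels, optionally restricted to a surviving edge subset
ji1_against <- function(cover, reference_labels, graph) {
  h <- contingency_counts(cover, reference_labels, graph, d = 1)
  jaccard_index(h)
}
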