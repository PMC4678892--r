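#' Pairwise filament roughness
#'
#' The mean absolute difference between the weights of adjacent edges along
#' a path,
#' \deqn{r_{pair}(p) = \frac{1}{P-1} \sum_{i=1}^{P-1} |w_{p,i+1} - w_{p,i}|,}
#' small when the intensity varies smoothly along the filament. A path of a
#' single edge scores its own edge weight; this convention penalises
#' fragmenting a network into single-edge filaments.
#'
#' @param path integer vector of node ids
#' @param graph a [filament_graph()]
#' @return non-negative numeric roughness value
#' @export
pairwise_roughness <- function(path, graph) {
  w <- path_weights(graph, path)
  if (length(w) == 1L) return(w)
  mean(abs(diff(w)))
}

#' All-to-all filament roughness
#'
#' The average maximal difference between any two edge weights in a path:
#' for each edge, take the largest absolute weight difference to any other
#' edge of the path, and average these maxima,
#' \deqn{r_{all}(p) = \frac{1}{P} \sum_{i=1}^{P} \max_j |w_{p,i} - w_{p,j}|.}
#' A single-edge path again scores its weight. Because an abrupt weight jump
#' (e.g. where overlapping filaments superpose) dominates every edge's
#' maximum, this measure penalises locally consistent but globally bimodal
#' filaments more than [pairwise_roughness()]. The `variant = "range"`
#' alternative reads "average maximal difference" as the plain weight range
#' `max(w) - min(w)`.
#'
#' @inheritParams pairwise_roughness
#' @param variant `"per_edge_max"` (default) or `"range"`
#' @return non-negative numeric roughness value
#' @export
all_to_all_roughness <- function(path, graph,
                                 variant = c("per_edge_max", "range")) {
  variant <- match.arg(variant)
  w <- path_weights(graph, path)
  if (length(w) == 1L) return(w)
  if (variant == "range") return(max(w) - min(w))
  mean(pmax(w - min(w), max(w) - w))
}

#' Euclidean angle between two vectors, in degrees
#'
#' @param u,v non-zero numeric vectors of equal length
#' @return angle in `[0, 180]` degrees; the normalised dot product is
#'   clipped to `[-1, 1]` before `acos` for floating-point safety.
#' @export
euclidean_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("geometry error: zero-length vector has no direction", call. = FALSE)
  }
  acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# unit-free segment vectors along a path, one row per edge, oriented in
# traversal direction (never by stored node order: deflection is
# direction-dependent)
path_segments <- function(graph, path) {
  pos <- node_pos(graph, path)
  seg <- pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  if (any(rowSums(seg^2) == 0)) {
    stop("geometry error: coincident consecutive node positions",
         call. = FALSE)
  }
  seg
}

#' Maximal deflection angle of a path
#'
#' Orients every edge along the traversal direction and returns the largest
#' Euclidean angle between consecutive segment vectors; 0 degrees means
#' perfectly straight alignment. A single-edge path deflects by 0.
#'
#' @inheritParams pairwise_roughness
#' @return angle in `[0, 180]` degrees
#' @export
max_deflection_angle <- function(path, graph) {
  validate_path(graph, path)
  seg <- path_segments(graph, path)
  P <- nrow(seg)
  if (P == 1L) return(0)
  max(vapply(seq_len(P - 1L), function(i) {
    euclidean_angle(seg[i, ], seg[i + 1L, ])
  }, numeric(1)))
}

# roughness of one path under the configured measure
path_roughness <- function(path, graph, measure = c("pair", "all"),
                           all_variant = "per_edge_max") {
  measure <- match.arg(measure)
  if (measure == "pair") pairwise_roughness(path, graph)
  else all_to_all_roughness(path, graph, variant = all_variant)
}

#' Total (or average) roughness of a cover
#'
#' @param cover a [filament_cover()]
#' @param graph the underlying [filament_graph()]
#' @param measure `"pair"` or `"all"`
#' @param objective `"total"` returns the sum of per-filament roughness
#'   values, `"avg"` the sum divided by the number of filaments.
#' @param all_variant passed to [all_to_all_roughness()]
#' @return numeric
#' @export
cover_roughness <- function(cover, graph, measure = c("pair", "all"),
                            objective = c("total", "avg"),
                            all_variant = "per_edge_max") {
  measure <- match.arg(measure)
  objective <- match.arg(objective)
  r <- vapply(cover$paths, path_roughness, numeric(1),
              graph = graph, measure = measure, all_variant = all_variant)
  if (objective == "total") sum(r) else sum(r) / length(r)
}
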