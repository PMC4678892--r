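#' Options controlling a filament-cover computation
#'
#' The decomposition has four categorical options, so all 2^4 = 16
#' combinations can be checked without tuning continuous parameters:
#' how candidate paths are sampled (`"bfs"` or `"rmst"`), whether filaments
#' may share edges (`"over"`) or must be edge-disjoint (`"exact"`), which
#' roughness functional scores a path (`"pair"` or `"all"`), and whether the
#' total or the average roughness of the cover is minimised.
#'
#' @param sampling `"bfs"` (angle-constrained breadth-first path search) or
#'   `"rmst"` (paths of random minimal spanning trees).
#' @param cover `"over"` (each edge covered at least once) or `"exact"`
#'   (exactly once).
#' @param roughness `"pair"` (mean absolute adjacent weight difference) or
#'   `"all"` (mean per-edge maximal weight difference).
#' @param objective `"total"` or `"avg"` roughness of the selected paths.
#' @param angle_max_deg straightness threshold in degrees; a candidate path
#'   is admissible only while its maximal deflection stays strictly below
#'   this value. Default 60, a tolerant bound for real filaments.
#' @param n_trees number of random minimal spanning trees for `"rmst"`
#'   sampling. Default 100.
#' @param seed integer seed for the tree sampler (and any other randomness);
#'   `NULL` leaves the RNG state alone.
#' @param all_variant how the `"all"` measure reads "average maximal
#'   difference": `"per_edge_max"` (mean over edges of each edge's maximal
#'   absolute difference to any other edge; the default) or `"range"`
#'   (max minus min).
#' @param max_paths safety cap on the number of BFS-enumerated paths.
#' @return a list of class `cover_options`.
#' @export
cover_options <- function(sampling = c("bfs", "rmst"),
                          cover = c("over", "exact"),
                          roughness = c("pair", "all"),
                          objective = c("total", "avg"),
                          angle_max_deg = 60,
                          n_trees = 100L,
                          seed = NULL,
                          all_variant = c("per_edge_max", "range"),
                          max_paths = 1e6) {
  sampling <- match.arg(sampling)
  cover <- match.arg(cover)
  roughness <- match.arg(roughness)
  objective <- match.arg(objective)
  all_variant <- match.arg(all_variant)
  stopifnot(is.numeric(angle_max_deg), length(angle_max_deg) == 1,
            angle_max_deg > 0, angle_max_deg < 180)
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L)
  structure(
    list(sampling = sampling, cover = cover, roughness = roughness,
         objective = objective, angle_max_deg = angle_max_deg,
         n_trees = n_trees, seed = seed, all_variant = all_variant,
         max_paths = max_paths),
    class = "cover_options"
  )
}

#' @export
print.cover_options <- function(x, ...) {
  cat(sprintf("<cover_options> %s / %s / %s / %s (angle < %g deg, T = %d)\n",
              x$sampling, x$cover, x$roughness, x$objective,
              x$angle_max_deg, x$n_trees))
  invisible(x)
}

#' Construct a filament cover
#'
#' A filament cover is a set of edge-paths such that every graph edge lies
#' on at least one path (exactly one for an exact cover). Filament ids are
#' 0-based positions in `paths`.
#'
#' @param paths list of node-id vectors (edge-paths).
#' @param graph the [filament_graph()] the paths live on.
#' @param options optional [cover_options()] that produced the cover.
#' @param total_roughness optional precomputed total roughness.
#' @param check validate covering and path invariants (default TRUE).
#' @return object of class `filament_cover`.
#' @export
filament_cover <- function(paths, graph, options = NULL,
                           total_roughness = NA_real_, check = TRUE) {
  stopifnot(is.list(paths), length(paths) > 0)
  paths <- lapply(paths, as.integer)
  if (check) {
    eids <- lapply(paths, function(p) validate_path(graph, p))
    counts <- tabulate(unlist(eids), nbins = n_edges(graph))
    if (any(counts == 0)) {
      i <- which(counts == 0)[1]
      stop(sprintf("not a cover: edge %d--%d uncovered",
                   graph$edges$from[i], graph$edges$to[i]), call. = FALSE)
    }
  }
  structure(
    list(paths = paths, options = options, total_roughness = total_roughness),
    class = "filament_cover"
  )
}

#' @export
print.filament_cover <- function(x, ...) {
  lens <- vapply(x$paths, function(p) length(p) - 1L, integer(1))
  cat(sprintf("<filament_cover> %d filaments, %d edge slots (R = %.6g)\n",
              length(x$paths), sum(lens), x$total_roughness))
  invisible(x)
}

#' Number of filaments in a cover
#' @param cover a [filament_cover()]
#' @return integer
#' @export
n_filaments <- function(cover) length(cover$paths)

#' Edge membership sets of a cover
#'
#' @param cover a [filament_cover()]
#' @param graph the underlying [filament_graph()]
#' @return object of class `edge_cover_labels`: a list with one integer
#'   vector of 0-based filament ids per graph edge (in `graph$edges` order).
#' @export
edge_cover_labels <- function(cover, graph) {
  E <- n_edges(graph)
  member <- vector("list", E)
  for (i in seq_along(cover$paths)) {
    for (e in path_edge_ids(graph, cover$paths[[i]])) {
      member[[e]] <- c(member[[e]], i - 1L)
    }
  }
  uncovered <- vapply(member, is.null, logical(1))
  if (any(uncovered)) {
    i <- which(uncovered)[1]
    stop(sprintf("not a cover: edge %d--%d uncovered",
                 graph$edges$from[i], graph$edges$to[i]), call. = FALSE)
  }
  structure(member, class = "edge_cover_labels")
}

#' Is a cover (or labelling) exact, i.e. free of overlaps?
#' @param labels an `edge_cover_labels` object
#' @return logical
#' @export
is_exact_labelling <- function(labels) {
  all(lengths(labels) == 1L)
}
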