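#' Convolutedness of a filament
#'
#' Ratio of the filament's geometric length to the largest side of the
#' axis-aligned bounding box of its nodes; 1 for a straight, axis-aligned
#' filament. The measure is deliberately kept in its conventional
#' bounding-box form, which is biased by the filament's orientation with
#' respect to the coordinate axes (a straight filament at 45 degrees scores
#' sqrt(2)); [max_deflection_angle()] is the orientation-free alternative
#' for local curvedness. A degenerate zero-extent box yields 1.
#'
#' @param path integer node-id vector
#' @param graph a [filament_graph()]
#' @return numeric `>= 1` (up to floating tolerance)
#' @export
convolutedness <- function(path, graph) {
  pos <- node_pos(graph, path)
  len <- sum(sqrt(rowSums((pos[-1, , drop = FALSE] -
                           pos[-nrow(pos), , drop = FALSE])^2)))
  side <- max(apply(pos, 2, function(v) diff(range(v))))
  if (side == 0) return(1)
  len / side
}

#' Median orientation of a filament relative to a reference axis
#'
#' For every edge, the acute angle in `[0, 90]` degrees between the edge
#' direction and the reference axis (folding makes the result invariant
#' under path reversal); returns the median over edges. Used to quantify
#' e.g. alignment of actin filaments with the cell axis.
#'
#' @inheritParams convolutedness
#' @param axis non-zero reference direction (default: x-axis)
#' @return angle in `[0, 90]` degrees
#' @export
median_orientation <- function(path, graph, axis = c(1, 0)) {
  if (graph$dim == 3L && length(axis) == 2) axis <- c(axis, 0)
  if (sqrt(sum(axis^2)) == 0) {
    stop("geometry error: zero-length reference axis", call. = FALSE)
  }
  seg <- path_segments(graph, path)
  ang <- apply(seg, 1, function(s) euclidean_angle(s, axis))
  ang <- pmin(ang, 180 - ang)
  stats::median(ang)
}

#' Per-filament descriptive metrics of a cover
#'
#' One record per filament: number of edges, geometric length (position
#' units), mean edge weight, both roughness measures, maximal deflection
#' angle, median orientation relative to `axis`, convolutedness, and the
#' node sequence.
#'
#' @param cover a [filament_cover()]
#' @param graph a [filament_graph()]
#' @param axis reference axis for [median_orientation()]
#' @return data.frame of class `filament_metrics`, one row per filament
#' @export
filament_metrics <- function(cover, graph, axis = c(1, 0)) {
  rows <- lapply(seq_along(cover$paths), function(i) {
    p <- cover$paths[[i]]
    w <- path_weights(graph, p)
    pos <- node_pos(graph, p)
    len <- sum(sqrt(rowSums((pos[-1, , drop = FALSE] -
                             pos[-nrow(pos), , drop = FALSE])^2)))
    data.frame(
      filament_id = i - 1L,
      n_edges = length(w),
      length_geometric = len,
      mean_weight = mean(w),
      roughness_pair = pairwise_roughness(p, graph),
      roughness_all = all_to_all_roughness(p, graph),
      max_angle_deg = max_deflection_angle(p, graph),
      median_orientation_deg = median_orientation(p, graph, axis = axis),
      convolutedness = convolutedness(p, graph),
      node_sequence = paste(p, collapse = "-")
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("filament_metrics", class(out))
  out
}

#' Total Euclidean length of each connected component
#'
#' Component length (the sum of its edge lengths) is the classical
#' filament-size proxy in studies that stop at connected components; it
#' overestimates individual filament lengths because components concatenate
#' filaments.
#'
#' @param graph a [filament_graph()]
#' @return numeric vector, one value per connected component
#' @export
component_lengths <- function(graph) {
  if (n_edges(graph) == 0) return(numeric(0))
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)$membership
  fr <- comp[node_row(graph, graph$edges$from)]
  lens <- edge_lengths(graph)
  as.numeric(tapply(lens, fr, sum))
}

#' Pearson correlations between filament metrics
#'
#' Correlation matrix of the numeric metric columns (standard Pearson
#' formula), e.g. to inspect how filament length relates to mean weight or
#' maximal angle.
#'
#' @param metrics a data.frame from [filament_metrics()]
#' @return correlation matrix
#' @export
metric_correlations <- function(metrics) {
  num <- metrics[, c("n_edges", "length_geometric", "mean_weight",
                     "roughness_pair", "roughness_all", "max_angle_deg",
                     "median_orientation_deg", "convolutedness")]
  stats::cor(num)
}
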