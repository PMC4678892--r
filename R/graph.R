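#' Construct a filament graph
#'
#' A filament graph is an undirected geometric graph: every node carries a
#' 2D (or 3D) position and every edge a positive weight encoding the local
#' intensity or thickness of the filament segment it represents. It is the
#' basic container on which candidate paths are sampled and filament covers
#' are computed.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`
#'   and optionally `z` (finite numerics). All nodes must have positions of
#'   the same dimensionality.
#' @param edges data.frame with columns `from`, `to` (node ids) and
#'   `weight` (positive finite numeric). Self-loops and parallel edges are
#'   rejected: the path and roughness machinery presupposes a simple graph,
#'   as holds for image-derived networks.
#' @return An object of class `filament_graph` with elements `nodes`
#'   (ids and positions), `edges` (endpoints stored with `from < to`, plus
#'   weight), and the dimensionality `dim`.
#' @examples
#' g <- filament_graph(
#'   nodes = data.frame(id = 0:2, x = c(0, 1, 2), y = c(0, 0, 0)),
#'   edges = data.frame(from = c(0, 1), to = c(1, 2), weight = c(0.5, 0.5))
#' )
#' g
#' @export
filament_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!all(c("id", "x", "y") %in% names(nodes))) {
    stop("`nodes` needs columns id, x, y (and optionally z)", call. = FALSE)
  }
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` needs columns from, to, weight", call. = FALSE)
  }
  if (!"weight" %in% names(edges)) {
    stop("format error: edges carry no 'weight' attribute", call. = FALSE)
  }
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  dim <- if ("z" %in% names(nodes) && !all(is.na(nodes$z))) 3L else 2L
  coord_cols <- c("x", "y", if (dim == 3L) "z")
  for (cc in coord_cols) {
    if (!all(is.finite(nodes[[cc]]))) {
      stop("format error: missing or non-finite node coordinate '", cc, "'",
           call. = FALSE)
    }
  }
  nodes <- nodes[, c("id", coord_cols)]

  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (nrow(edges) > 0) {
    bad <- !is.finite(edges$weight) | edges$weight <= 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("format error: edge %d--%d has missing or non-positive weight",
                   edges$from[i], edges$to[i]), call. = FALSE)
    }
    if (any(edges$from == edges$to)) {
      i <- which(edges$from == edges$to)[1]
      stop(sprintf("validation error: self-loop at node %d", edges$from[i]),
           call. = FALSE)
    }
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    edges$from <- lo
    edges$to <- hi
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop(sprintf("validation error: parallel edge %d--%d",
                   edges$from[i], edges$to[i]), call. = FALSE)
    }
    missing_node <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing_node) > 0) {
      stop(sprintf("validation error: edge references unknown node %d",
                   missing_node[1]), call. = FALSE)
    }
  }
  extra <- setdiff(names(edges), c("from", "to", "weight"))
  edges <- edges[, c("from", "to", "weight", extra)]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, dim = dim),
    class = "filament_graph"
  )
}

#' @export
print.filament_graph <- function(x, ...) {
  cat(sprintf("<filament_graph> %d nodes, %d edges (%dD)\n",
              nrow(x$nodes), nrow(x$edges), x$dim))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  edge weights in [%.4g, %.4g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

n_edges <- function(graph) nrow(graph$edges)
n_nodes <- function(graph) nrow(graph$nodes)

# row indices into graph$nodes for a vector of node ids
node_row <- function(graph, ids) {
  r <- match(ids, graph$nodes$id)
  if (anyNA(r)) stop("unknown node id: ", ids[which(is.na(r))[1]], call. = FALSE)
  r
}

# positions of nodes (matrix, one row per id)
node_pos <- function(graph, ids) {
  cols <- c("x", "y", if (graph$dim == 3L) "z")
  as.matrix(graph$nodes[node_row(graph, ids), cols, drop = FALSE])
}

edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v))

#' Edge indices along a path
#'
#' @param graph a [filament_graph()]
#' @param path integer vector of node ids; consecutive ids must be joined by
#'   an edge of `graph`. A closed path repeats its start node at the end.
#' @return integer vector of edge indices (rows of `graph$edges`).
#' @keywords internal
path_edge_ids <- function(graph, path) {
  if (length(path) < 2) stop("a path needs at least two nodes", call. = FALSE)
  u <- path[-length(path)]
  v <- path[-1]
  ids <- match(edge_key(u, v), edge_key(graph$edges$from, graph$edges$to))
  if (anyNA(ids)) {
    i <- which(is.na(ids))[1]
    stop(sprintf("no edge %d--%d in graph", u[i], v[i]), call. = FALSE)
  }
  ids
}

# edge weights in traversal order
path_weights <- function(graph, path) {
  graph$edges$weight[path_edge_ids(graph, path)]
}

is_closed_path <- function(path) {
  length(path) >= 3 && path[1] == path[length(path)]
}

#' Validate an edge-path
#'
#' Checks the edge-path invariants: consecutive edges share a node (implied
#' by the node-sequence encoding), every consecutive pair is an actual graph
#' edge, and no edge is used twice. Node revisits are allowed (a filament may
#' cross itself); only the closing node of a loop repeats the start.
#'
#' @inheritParams path_edge_ids
#' @return invisibly, the edge indices of the path.
#' @export
validate_path <- function(graph, path) {
  ids <- path_edge_ids(graph, path)
  if (anyDuplicated(ids)) {
    stop("invalid path: an edge appears twice", call. = FALSE)
  }
  invisible(ids)
}

#' Convert to an igraph object
#'
#' Used internally for spanning trees, shortest-path distances and connected
#' components. Vertex order follows `graph$nodes`; the vertex attribute
#' `name` holds the node id as character.
#'
#' @param graph a [filament_graph()]
#' @return an [igraph::graph] object with edge attribute `weight`.
#' @export
as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph$edges$from),
                   to = as.character(graph$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$id))
  )
  igraph::E(ig)$weight <- graph$edges$weight
  ig
}

# Euclidean length of every edge
edge_lengths <- function(graph) {
  if (nrow(graph$edges) == 0) return(numeric(0))
  a <- node_pos(graph, graph$edges$from)
  b <- node_pos(graph, graph$edges$to)
  sqrt(rowSums((a - b)^2))
}
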