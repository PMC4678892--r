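# Minimal GML tokenizer/parser. GML is a line-oriented key-value format
# with nested bracketed blocks; node coordinates occur in the wild both as
# top-level x/y(/z) attributes and nested inside a graphics [ ... ] block,
# so both dialects are accepted here. (The igraph reader discards nested
# blocks, hence this dedicated parser.)

gml_tokenize <- function(text) {
  text <- gsub("#[^\n]*", "", text) # strip comments
  m <- gregexpr('"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+', text, perl = TRUE)
  regmatches(text, m)[[1]]
}

# parse a token stream into nested list-of-(key, value) pairs
gml_parse_block <- function(tokens, pos) {
  entries <- list()
  n <- length(tokens)
  while (pos <= n) {
    key <- tokens[pos]
    if (key == "]") return(list(entries = entries, pos = pos + 1L))
    if (pos + 1L > n) stop("GML format error: dangling key '", key, "'",
                           call. = FALSE)
    val <- tokens[pos + 1L]
    if (val == "[") {
      sub <- gml_parse_block(tokens, pos + 2L)
      entries[[length(entries) + 1L]] <- list(key = key, value = sub$entries)
      pos <- sub$pos
    } else {
      if (startsWith(val, '"')) {
        v <- substr(val, 2L, nchar(val) - 1L)
      } else {
        num <- suppressWarnings(as.numeric(val))
        v <- if (is.na(num)) val else num
      }
      entries[[length(entries) + 1L]] <- list(key = key, value = v)
      pos <- pos + 2L
    }
  }
  list(entries = entries, pos = pos)
}

gml_get <- function(entries, key) {
  for (e in entries) if (e$key == key) return(e$value)
  NULL
}

gml_get_all <- function(entries, key) {
  Filter(Negate(is.null), lapply(entries, function(e) {
    if (e$key == key) e$value else NULL
  }))
}

# coordinate lookup honouring both dialects
gml_node_coord <- function(node, axis) {
  v <- gml_get(node, axis)
  if (is.null(v)) {
    gr <- gml_get(node, "graphics")
    if (!is.null(gr)) v <- gml_get(gr, axis)
  }
  v
}

#' Read a weighted geometric graph from a GML file
#'
#' Nodes must carry an integer `id` and coordinates `x`, `y` (optionally
#' `z`), either as top-level attributes or nested inside a `graphics`
#' block. Edges must carry `source`, `target` and a positive `weight`.
#' Edge weights are not rescaled on load: the single-edge roughness
#' convention makes results scale-dependent, so normalisation (e.g. to a
#' maximum of 1) is left to the caller.
#'
#' If edges carry a `filaments` attribute (semicolon-joined filament ids,
#' as written by [write_cover_gml()]), it is retained in the returned edge
#' table so a reference assignment can be recovered with
#' [labels_from_gml_graph()].
#'
#' @param file_path path to a GML file
#' @return a [filament_graph()]
#' @export
read_gml <- function(file_path) {
  if (!file.exists(file_path)) {
    stop("input error: no such file: ", file_path, call. = FALSE)
  }
  tokens <- gml_tokenize(paste(readLines(file_path, warn = FALSE),
                               collapse = "\n"))
  top <- gml_parse_block(tokens, 1L)$entries
  graph_block <- gml_get(top, "graph")
  if (is.null(graph_block)) {
    stop("GML format error: no 'graph' block in ", file_path, call. = FALSE)
  }
  nodes <- gml_get_all(graph_block, "node")
  edges <- gml_get_all(graph_block, "edge")
  if (length(nodes) == 0) stop("GML format error: no nodes", call. = FALSE)

  node_df <- do.call(rbind, lapply(nodes, function(nd) {
    id <- gml_get(nd, "id")
    if (is.null(id)) stop("GML format error: node without id", call. = FALSE)
    x <- gml_node_coord(nd, "x")
    y <- gml_node_coord(nd, "y")
    z <- gml_node_coord(nd, "z")
    if (is.null(x) || is.null(y)) {
      stop(sprintf("GML format error: node %d has missing coordinates", id),
           call. = FALSE)
    }
    data.frame(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
               z = if (is.null(z)) NA_real_ else as.numeric(z))
  }))
  has_z <- !anyNA(node_df$z)
  if (!has_z && !all(is.na(node_df$z))) {
    stop("GML format error: mixed 2D/3D node coordinates", call. = FALSE)
  }
  if (!has_z) node_df$z <- NULL

  edge_df <- do.call(rbind, lapply(edges, function(ed) {
    s <- gml_get(ed, "source")
    t <- gml_get(ed, "target")
    w <- gml_get(ed, "weight")
    if (is.null(s) || is.null(t)) {
      stop("GML format error: edge without source/target", call. = FALSE)
    }
    if (is.null(w)) {
      stop(sprintf("GML format error: edge %d--%d has no 'weight' attribute",
                   as.integer(s), as.integer(t)), call. = FALSE)
    }
    fil <- gml_get(ed, "filaments")
    data.frame(from = as.integer(s), to = as.integer(t),
               weight = as.numeric(w),
               filaments = if (is.null(fil)) NA_character_
                           else as.character(fil))
  }))
  if (is.null(edge_df)) {
    edge_df <- data.frame(from = integer(0), to = integer(0),
                          weight = numeric(0))
  } else if (all(is.na(edge_df$filaments))) {
    edge_df$filaments <- NULL
  }
  filament_graph(node_df, edge_df)
}

#' Recover edge labels from a GML-stored filament assignment
#'
#' @param graph a [filament_graph()] read with [read_gml()] whose edges
#'   carry a `filaments` column
#' @return an `edge_cover_labels` object
#' @export
labels_from_gml_graph <- function(graph) {
  if (is.null(graph$edges$filaments) || anyNA(graph$edges$filaments)) {
    stop("graph carries no filament assignment (missing 'filaments' edge attribute)",
         call. = FALSE)
  }
  structure(
    lapply(strsplit(graph$edges$filaments, ";", fixed = TRUE), as.integer),
    class = "edge_cover_labels"
  )
}

fmt_num <- function(x) {
  # 6 significant digits, reproducible text form
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(round(v))))
    formatC(signif(v, 6), format = "g", digits = 6)
  }, character(1))
}

#' Write a graph (optionally with a filament cover) to GML
#'
#' Emits the graph with top-level node coordinates and, when a cover is
#' given, two attributes per edge: `filaments`, the semicolon-joined sorted
#' ids of all filaments covering the edge, and `filament`, the lowest
#' covering id, which serves as a colour key. Numbers are printed with 6
#' significant digits for reproducible text diffs.
#'
#' @param graph a [filament_graph()]
#' @param cover a [filament_cover()] over `graph`, or `NULL` for a plain
#'   graph
#' @param file_path output path
#' @return invisibly, `file_path`
#' @export
write_cover_gml <- function(graph, cover = NULL, file_path) {
  labels <- if (!is.null(cover)) {
    tryCatch(edge_cover_labels(cover, graph), error = function(e) {
      stop("consistency error: ", conditionMessage(e), call. = FALSE)
    })
  }
  con <- file(file_path, open = "wt")
  on.exit(close(con))
  out <- function(...) writeLines(paste0(...), con)
  out("graph [")
  out("  directed 0")
  for (i in seq_len(nrow(graph$nodes))) {
    out("  node [")
    out("    id ", graph$nodes$id[i])
    out("    x ", fmt_num(graph$nodes$x[i]))
    out("    y ", fmt_num(graph$nodes$y[i]))
    if (graph$dim == 3L) out("    z ", fmt_num(graph$nodes$z[i]))
    out("  ]")
  }
  for (e in seq_len(n_edges(graph))) {
    out("  edge [")
    out("    source ", graph$edges$from[e])
    out("    target ", graph$edges$to[e])
    out("    weight ", fmt_num(graph$edges$weight[e]))
    if (!is.null(labels)) {
      ids <- sort(labels[[e]])
      out("    filaments \"", paste(ids, collapse = ";"), "\"")
      out("    filament ", ids[1])
    }
    out("  ]")
  }
  out("]")
  invisible(file_path)
}

#' Write per-filament metrics to CSV
#'
#' Fixed 10-column schema (filament_id, n_edges, length_geometric,
#' mean_weight, roughness_pair, roughness_all, max_angle_deg,
#' median_orientation_deg, convolutedness, node_sequence), one row per
#' filament, numbers at 6 significant digits; byte-stable across runs for
#' identical input. Lines starting with `#` (e.g. a seed/options header
#' written by the command-line tool) precede the column header.
#'
#' @param metrics non-empty data.frame from [filament_metrics()]
#' @param file_path output path
#' @param header_comments optional character vector written as `#` comment
#'   lines before the header
#' @return invisibly, `file_path`
#' @export
write_filament_csv <- function(metrics, file_path, header_comments = NULL) {
  cols <- c("filament_id", "n_edges", "length_geometric", "mean_weight",
            "roughness_pair", "roughness_all", "max_angle_deg",
            "median_orientation_deg", "convolutedness", "node_sequence")
  if (is.null(metrics) || nrow(metrics) == 0) {
    stop("metrics must contain at least one filament", call. = FALSE)
  }
  stopifnot(all(cols %in% names(metrics)))
  m <- metrics[, cols]
  for (cc in setdiff(cols, c("filament_id", "n_edges", "node_sequence"))) {
    m[[cc]] <- fmt_num(m[[cc]])
  }
  con <- file(file_path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  writeLines(paste(cols, collapse = ","), con)
  writeLines(do.call(paste, c(m, sep = ",")), con)
  invisible(file_path)
}
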