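# Planted-scene generation: filaments are drawn as polylines ("strokes"),
# crossings between strokes are turned into shared nodes, overlap runs
# share node sequences, and edge weights follow an additive intensity
# model. The planted cover is the ground truth against which automated
# decompositions are scored.

#' Parameters of a random planted scene
#'
#' @param n_filaments number of filaments to draw
#' @param n_segments_range integer range of segments per open filament
#' @param turn_max_deg strict bound on the turning angle between successive
#'   segments of a planted filament; keep it below the downstream
#'   straightness threshold so every planted filament is BFS-admissible.
#' @param p_overlap probability that a filament is routed along an edge run
#'   of a previously drawn filament (shared edges)
#' @param p_loop probability that a filament closes into a loop
#' @param base_intensity_range interval within (0, 1] for per-filament base
#'   intensities
#' @param weight_noise_sd standard deviation of the additive centred
#'   Gaussian weight noise
#' @param seed integer seed; the whole scene is reproducible from
#'   `(params, seed)`
#' @return a list of class `scene_params`
#' @export
scene_params <- function(n_filaments = 6L,
                         n_segments_range = c(5L, 9L),
                         turn_max_deg = 45,
                         p_overlap = 0.2,
                         p_loop = 0.15,
                         base_intensity_range = c(0.65, 0.95),
                         weight_noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(n_filaments >= 1, turn_max_deg > 0, turn_max_deg < 180,
            p_overlap >= 0, p_overlap <= 1, p_loop >= 0, p_loop <= 1,
            length(base_intensity_range) == 2,
            base_intensity_range[1] > 0, base_intensity_range[2] <= 1,
            weight_noise_sd >= 0)
  structure(
    list(n_filaments = as.integer(n_filaments),
         n_segments_range = as.integer(n_segments_range),
         turn_max_deg = turn_max_deg, p_overlap = p_overlap,
         p_loop = p_loop, base_intensity_range = base_intensity_range,
         weight_noise_sd = weight_noise_sd, seed = as.integer(seed)),
    class = "scene_params"
  )
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# proper interior intersection of segments (p1,p2) and (q1,q2);
# returns NULL or list(point, t, s)
seg_intersect <- function(p1, p2, q1, q2, margin = 0.03) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-9) return(NULL)
  b <- q1 - p1
  t <- (b[1] * d2[2] - b[2] * d2[1]) / det
  s <- (b[1] * d1[2] - b[2] * d1[1]) / det
  if (t <= margin || t >= 1 - margin || s <= margin || s >= 1 - margin) {
    return(NULL)
  }
  list(point = p1 + t * d1, t = t, s = s)
}

# ---- stroke assembly -------------------------------------------------------
# strokes: list of list(coords = (k+1) x 2 matrix, closed = flag,
#                       shared_with = host index or NA)
# Shared runs are encoded by exact coordinate reuse; the node registry merges
# coincident points into a single node id.

assemble_scene <- function(strokes, base_intensity, weight_noise_sd) {
  # split stroke segments at pairwise crossings
  refined <- lapply(strokes, function(s) s$coords)
  n <- length(refined)
  cuts <- vector("list", n) # per stroke: list of (segment index, t, point)
  for (i in seq_len(n)) cuts[[i]] <- list()
  seg_list <- function(coords) {
    k <- nrow(coords) - 1L
    lapply(seq_len(k), function(j) list(a = coords[j, ], b = coords[j + 1L, ]))
  }
  for (i in seq_len(n - 1L)) {
    si <- seg_list(refined[[i]])
    for (j in (i + 1L):n) {
      sj <- seg_list(refined[[j]])
      for (a in seq_along(si)) {
        for (b in seq_along(sj)) {
          # skip segment pairs that share an endpoint (junctions, overlaps)
          if (min(sqrt(sum((si[[a]]$a - sj[[b]]$a)^2)),
                  sqrt(sum((si[[a]]$a - sj[[b]]$b)^2)),
                  sqrt(sum((si[[a]]$b - sj[[b]]$a)^2)),
                  sqrt(sum((si[[a]]$b - sj[[b]]$b)^2))) < 1e-9) next
          hit <- seg_intersect(si[[a]]$a, si[[a]]$b, sj[[b]]$a, sj[[b]]$b)
          if (!is.null(hit)) {
            cuts[[i]][[length(cuts[[i]]) + 1L]] <-
              list(seg = a, t = hit$t, point = hit$point)
            cuts[[j]][[length(cuts[[j]]) + 1L]] <-
              list(seg = b, t = hit$s, point = hit$point)
          }
        }
      }
    }
  }
  for (i in seq_len(n)) {
    if (length(cuts[[i]]) == 0) next
    coords <- refined[[i]]
    segs <- vapply(cuts[[i]], function(cu) cu$seg, numeric(1))
    ts <- vapply(cuts[[i]], function(cu) cu$t, numeric(1))
    newc <- coords[1, , drop = FALSE]
    for (j in seq_len(nrow(coords) - 1L)) {
      sel <- which(segs == j)
      if (length(sel) > 0) {
        for (k in sel[order(ts[sel])]) {
          pt <- cuts[[i]][[k]]$point
          # the same geometric crossing may be reported once per stroke
          # pair (e.g. against both members of an overlap run): keep one
          if (sqrt(sum((pt - newc[nrow(newc), ])^2)) > 1e-9) {
            newc <- rbind(newc, pt)
          }
        }
      }
      newc <- rbind(newc, coords[j + 1L, ])
    }
    refined[[i]] <- newc
  }

  # node registry keyed by rounded coordinates
  reg <- new.env(hash = TRUE, parent = emptyenv())
  coords_out <- list()
  next_id <- 0L
  get_node <- function(pt) {
    key <- paste(round(pt[1], 7), round(pt[2], 7))
    id <- reg[[key]]
    if (is.null(id)) {
      id <- next_id
      next_id <<- next_id + 1L
      reg[[key]] <- id
      coords_out[[id + 1L]] <<- pt
    }
    id
  }
  paths <- lapply(refined, function(coords) {
    vapply(seq_len(nrow(coords)), function(j) get_node(coords[j, ]),
           integer(1))
  })
  for (i in seq_len(n)) {
    if (strokes[[i]]$closed) paths[[i]] <- c(paths[[i]], paths[[i]][1])
  }

  pos <- do.call(rbind, coords_out)
  nodes <- data.frame(id = seq_len(nrow(pos)) - 1L,
                      x = pos[, 1], y = pos[, 2])

  # edge table + planted membership
  ekey_env <- new.env(hash = TRUE, parent = emptyenv())
  from <- integer(0); to <- integer(0); cover_sum <- numeric(0)
  add_edge <- function(u, v, b) {
    key <- paste(min(u, v), max(u, v))
    idx <- ekey_env[[key]]
    if (is.null(idx)) {
      from <<- c(from, min(u, v)); to <<- c(to, max(u, v))
      cover_sum <<- c(cover_sum, 0)
      idx <- length(from)
      ekey_env[[key]] <- idx
    }
    cover_sum[idx] <<- cover_sum[idx] + b
    idx
  }
  for (i in seq_len(n)) {
    p <- paths[[i]]
    for (j in seq_len(length(p) - 1L)) add_edge(p[j], p[j + 1L], base_intensity[i])
  }
  w <- pmin(1, cover_sum)
  if (weight_noise_sd > 0) {
    w <- w + stats::rnorm(length(w), 0, weight_noise_sd)
  }
  w <- pmax(w, 1e-6)
  graph <- filament_graph(nodes,
                          data.frame(from = from, to = to, weight = w))
  cover <- filament_cover(paths, graph, check = TRUE)
  list(graph = graph, cover = cover, base_intensity = base_intensity)
}

# random open polyline with bounded turning
random_polyline <- function(n_seg, turn_max_deg, box = c(0, 12)) {
  start <- stats::runif(2, box[1] + 2, box[2] - 2)
  ang <- stats::runif(1, 0, 360)
  pts <- matrix(start, nrow = 1)
  for (j in seq_len(n_seg)) {
    ang <- ang + stats::runif(1, -0.85, 0.85) * turn_max_deg
    step <- stats::runif(1, 0.8, 1.2)
    pts <- rbind(pts, pts[nrow(pts), ] +
                   step * c(cos(ang * pi / 180), sin(ang * pi / 180)))
  }
  pts
}

# regular polygon with enough vertices that every deflection (including the
# seam) stays strictly below turn_max_deg
loop_polygon <- function(turn_max_deg, box = c(0, 12)) {
  k <- max(ceiling(360 / turn_max_deg) + 2L, 8L)
  r <- stats::runif(1, 1.3, 2.0)
  ctr <- stats::runif(2, box[1] + 3, box[2] - 3)
  phase <- stats::runif(1, 0, 2 * pi)
  th <- phase + 2 * pi * (seq_len(k) - 1) / k
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

# route a new filament along a middle run of a host stroke: one entry edge,
# the shared run (coordinates reused exactly), one exit edge
overlap_stroke <- function(host_coords, run_len = 3L, turn_deg = 30) {
  k <- nrow(host_coords) - 1L
  if (k < run_len + 2L) return(NULL)
  s0 <- sample(2:(k - run_len), 1)
  run <- host_coords[s0:(s0 + run_len), , drop = FALSE]
  d_in <- run[2, ] - run[1, ]
  d_in <- d_in / sqrt(sum(d_in^2))
  d_out <- run[nrow(run), ] - run[nrow(run) - 1L, ]
  d_out <- d_out / sqrt(sum(d_out^2))
  side <- sample(c(-1, 1), 1)
  entry <- run[1, ] - as.numeric(rot2(side * turn_deg) %*% d_in)
  exit <- run[nrow(run), ] + as.numeric(rot2(-side * turn_deg) %*% d_out)
  rbind(entry, run, exit)
}

#' Generate a random planted filamentous scene
#'
#' Draws each filament as a polyline with bounded turning angle (closed
#' into a loop with probability `p_loop`); with probability `p_overlap` a
#' filament is instead routed along an edge run of an earlier filament,
#' sharing those edges. Wherever two polylines cross, a node is inserted at
#' the intersection, splitting both edges. Each filament receives a base
#' intensity drawn uniformly from `base_intensity_range`; an edge's weight
#' is `min(1, sum of covering base intensities)` plus centred Gaussian
#' noise, floored at a small positive value. The additive, clipped
#' intensity model mirrors the abrupt apparent-thickness increase where
#' physical filaments superpose.
#'
#' @param params a [scene_params()]
#' @return list with elements `graph` (a [filament_graph()]), `cover` (the
#'   planted ground-truth [filament_cover()]), and `base_intensity`.
#' @export
generate_scene <- function(params = scene_params()) {
  set.seed(params$seed)
  for (attempt in 1:8) {
    res <- try(generate_scene_once(params), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("generation error: no valid scene after 8 attempts: ",
       attr(res, "condition")$message, call. = FALSE)
}

generate_scene_once <- function(params) {
  strokes <- list()
  b <- stats::runif(params$n_filaments, params$base_intensity_range[1],
                    params$base_intensity_range[2])
  for (i in seq_len(params$n_filaments)) {
    u <- stats::runif(1)
    open_hosts <- which(vapply(strokes, function(s) {
      !s$closed && is.na(s$shared_with) && nrow(s$coords) >= 6
    }, logical(1)))
    if (u < params$p_loop) {
      strokes[[i]] <- list(coords = loop_polygon(params$turn_max_deg),
                           closed = TRUE, shared_with = NA_integer_)
    } else if (u < params$p_loop + params$p_overlap &&
               length(open_hosts) > 0) {
      host <- sample(open_hosts, 1)
      ov <- overlap_stroke(strokes[[host]]$coords)
      if (is.null(ov)) {
        strokes[[i]] <- list(coords = random_polyline(
          sample(params$n_segments_range[1]:params$n_segments_range[2], 1),
          params$turn_max_deg), closed = FALSE, shared_with = NA_integer_)
      } else {
        strokes[[i]] <- list(coords = ov, closed = FALSE,
                             shared_with = host)
      }
    } else {
      strokes[[i]] <- list(coords = random_polyline(
        sample(params$n_segments_range[1]:params$n_segments_range[2], 1),
        params$turn_max_deg), closed = FALSE, shared_with = NA_integer_)
    }
  }
  assemble_scene(strokes, b, params$weight_noise_sd)
}

#' The contrived benchmark scene: crossings, a shared-run overlap, a loop
#'
#' A fixed hand-designed layout emulating a drawn artificial filament
#' network: four long open filaments with near-perpendicular crossings, one
#' pair of filaments sharing a three-edge run (entered and left at 30
#' degrees through single-edge connectors), and one closed loop. All
#' planted turning angles stay below `turn_max_deg` (default 45 degrees) so
#' the full planted cover is contained in any BFS candidate set with the
#' standard 60-degree straightness threshold, while every crossing meets at
#' 60-120 degrees so no admissible candidate path mixes crossing filaments.
#' Only the per-filament base intensities and the weight noise depend on
#' the seed; the geometry is fixed, as for a drawn test image.
#'
#' @param seed integer seed for intensities and noise
#' @param weight_noise_sd additive Gaussian weight noise (default 0.02)
#' @param base_intensity_range interval for base intensities
#' @param turn_max_deg maximal planted turning angle (degrees)
#' @return same structure as [generate_scene()]
#' @export
contrived_scene <- function(seed = 1L, weight_noise_sd = 0.02,
                            base_intensity_range = c(0.65, 0.95),
                            turn_max_deg = 45) {
  set.seed(seed)
  walk <- function(start, angles_deg, step = 1) {
    pts <- matrix(start, nrow = 1)
    for (a in angles_deg) {
      pts <- rbind(pts, pts[nrow(pts), ] +
                     step * c(cos(a * pi / 180), sin(a * pi / 180)))
    }
    pts
  }
  strokes <- list()
  # F1: long, gently wavy, left to right across the scene
  strokes[[1]] <- list(coords = walk(c(0, 4.6), c(5, -8, 10, -6, 8, -10, 6,
                                                  -4, 8, -8, 5, -5, 8, -6)),
                       closed = FALSE, shared_with = NA_integer_)
  # F2, F3: upward filaments crossing F1 nearly perpendicularly
  strokes[[2]] <- list(coords = walk(c(2.6, 0.2), c(88, 96, 84, 92, 86, 94,
                                                    88, 90, 94, 86)),
                       closed = FALSE, shared_with = NA_integer_)
  strokes[[3]] <- list(coords = walk(c(6.4, 0.4), c(92, 84, 95, 88, 92, 85,
                                                    90, 95, 87, 91)),
                       closed = FALSE, shared_with = NA_integer_)
  # F4: oblique filament, crossing angles with F1 kept in [60, 120]
  strokes[[4]] <- list(coords = walk(c(10.6, 0.0), c(108, 116, 110, 104, 112,
                                                     118, 108, 112, 106, 110)),
                       closed = FALSE, shared_with = NA_integer_)
  # F5/F6: overlap pair sharing a horizontal three-edge run
  run <- walk(c(2.2, 8.6), c(6, -6, 4))
  entry5 <- run[1, ] - c(cos(36 * pi / 180), sin(36 * pi / 180))
  exit5 <- run[4, ] + c(cos(-26 * pi / 180), sin(-26 * pi / 180))
  entry6 <- run[1, ] - c(cos(-24 * pi / 180), sin(-24 * pi / 180))
  exit6 <- run[4, ] + c(cos(34 * pi / 180), sin(34 * pi / 180))
  strokes[[5]] <- list(coords = rbind(entry5, run, exit5),
                       closed = FALSE, shared_with = NA_integer_)
  strokes[[6]] <- list(coords = rbind(entry6, run, exit6),
                       closed = FALSE, shared_with = 5L)
  # F7: closed loop (12-gon, 30 degree deflections)
  th <- 2 * pi * (0:11) / 12
  strokes[[7]] <- list(coords = cbind(9.3 + 1.7 * cos(th),
                                      8.3 + 1.7 * sin(th)),
                       closed = TRUE, shared_with = NA_integer_)
  b <- stats::runif(7, base_intensity_range[1], base_intensity_range[2])
  assemble_scene(strokes, b, weight_noise_sd)
}

#' Perturb edge weights with relative Gaussian noise
#'
#' Each weight is perturbed independently by centred Gaussian noise with
#' standard deviation `sd_fraction` times the weight, then floored at a
#' small positive value; topology and positions are untouched and the
#' input graph is not modified.
#'
#' @param graph a [filament_graph()]
#' @param sd_fraction noise standard deviation as a fraction of each weight
#' @param seed optional integer seed
#' @return a new [filament_graph()]
#' @export
add_weight_noise <- function(graph, sd_fraction, seed = NULL) {
  stopifnot(sd_fraction >= 0)
  if (!is.null(seed)) set.seed(seed)
  g2 <- graph
  if (sd_fraction > 0 && n_edges(graph) > 0) {
    w <- graph$edges$weight
    g2$edges$weight <- pmax(w + stats::rnorm(length(w), 0, sd_fraction * w),
                            1e-6)
  }
  g2
}

#' Remove k random edges from a graph
#'
#' Samples `k` distinct edges uniformly without replacement and deletes
#' them; isolated nodes are retained.
#'
#' @param graph a [filament_graph()]
#' @param k number of edges to remove, `0 <= k < E`
#' @param seed optional integer seed
#' @return a new [filament_graph()]
#' @export
remove_random_edges <- function(graph, k, seed = NULL) {
  E <- n_edges(graph)
  if (k < 0 || k >= E) {
    stop("parameter error: k must satisfy 0 <= k < E", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (k == 0) return(graph)
  drop <- sample.int(E, k)
  g2 <- graph
  g2$edges <- graph$edges[-drop, , drop = FALSE]
  rownames(g2$edges) <- NULL
  g2
}

# restrict reference labels (and cut reference paths) to a damaged graph:
# returns edge_cover_labels on the subgraph's edge order
restrict_labels <- function(reference, graph, subgraph) {
  labels <- as_edge_labels(reference, graph)
  key_old <- edge_key(graph$edges$from, graph$edges$to)
  key_new <- edge_key(subgraph$edges$from, subgraph$edges$to)
  idx <- match(key_new, key_old)
  structure(labels[idx], class = "edge_cover_labels")
}

solve_ji1 <- function(graph, reference_labels, options) {
  cov <- solve_fcp(graph, options)
  ji1_against(cov, reference_labels, graph)
}

#' Edge-removal robustness protocol
#'
#' For each `k` in `1..k_max`, deletes `samples_per_k` random subsets of
#' `k` edges, recomputes the optimal filament cover of every damaged graph,
#' and scores its structure-aware Jaccard agreement (JI at distance bound
#' 1) against the reference cover restricted to the surviving edges. The
#' `k = 0` row holds the unperturbed baseline.
#'
#' @param graph a [filament_graph()]
#' @param reference the ground-truth [filament_cover()] of `graph`
#' @param options [cover_options()] used for every re-solve
#' @param k_max largest removed subset (default 50)
#' @param samples_per_k random subsets per `k`
#' @param seed integer seed
#' @param k_values optional explicit vector of `k` values (overrides
#'   `1:k_max`)
#' @return data.frame with columns `k`, `mean_ji1`
#' @export
edge_removal_curve <- function(graph, reference, options = cover_options(),
                               k_max = 50L, samples_per_k = 3L, seed = 1L,
                               k_values = NULL) {
  ref_labels <- as_edge_labels(reference, graph)
  base <- solve_ji1(graph, ref_labels, options)
  ks <- if (is.null(k_values)) seq_len(min(k_max, n_edges(graph) - 1L))
        else k_values
  rows <- lapply(ks, function(k) {
    jis <- vapply(seq_len(samples_per_k), function(s) {
      g2 <- remove_random_edges(graph, k, seed = seed + 1000L * k + s)
      solve_ji1(g2, restrict_labels(ref_labels, graph, g2), options)
    }, numeric(1))
    data.frame(k = k, mean_ji1 = mean(jis, na.rm = TRUE))
  })
  rbind(data.frame(k = 0L, mean_ji1 = base), do.call(rbind, rows))
}

#' Weight-noise robustness protocol
#'
#' For each noise level, perturbs the edge weights of `n_instances`
#' independent copies of the graph with relative Gaussian noise, recomputes
#' the optimal filament cover of each, and averages the structure-aware
#' Jaccard agreement (JI at distance bound 1) with the reference. Because
#' noise leaves the topology untouched, the candidate path set is sampled
#' once and only the path costs are recomputed per instance.
#'
#' @inheritParams edge_removal_curve
#' @param sd_levels noise standard deviations as fractions of the edge
#'   weights (e.g. 0.05 for 5 percent)
#' @param n_instances noisy instances per level (default 100)
#' @return data.frame with columns `sd`, `mean_ji1`
#' @export
noise_robustness_curve <- function(graph, reference,
                                   options = cover_options(),
                                   sd_levels = c(0, 0.05, 0.1, 0.2),
                                   n_instances = 100L, seed = 1L) {
  ref_labels <- as_edge_labels(reference, graph)
  candidates <- sample_paths(graph, options)
  base_program <- build_cover_program(candidates, graph, options)
  solve_with_weights <- function(g) {
    program <- base_program
    program$graph <- g
    program$costs <- costs_from_weights(program$path_edges, g$edges$weight,
                                        options$roughness,
                                        options$all_variant)
    cov <- if (options$objective == "total") solve_total(program)
           else solve_average(program)
    ji1_against(cov, ref_labels, g)
  }
  rows <- lapply(seq_along(sd_levels), function(li) {
    sd <- sd_levels[li]
    if (sd == 0) {
      ji <- solve_with_weights(graph)
      return(data.frame(sd = sd, mean_ji1 = ji))
    }
    jis <- vapply(seq_len(n_instances), function(s) {
      g2 <- add_weight_noise(graph, sd, seed = seed + 10000L * li + s)
      solve_with_weights(g2)
    }, numeric(1))
    data.frame(sd = sd, mean_ji1 = mean(jis))
  })
  do.call(rbind, rows)
}
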