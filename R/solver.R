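#' Build the set-cover program for a candidate path set
#'
#' Translates candidates into the binary program
#' \deqn{\min \sum_p r_p x_p \; / \; (\sum_p x_p)^A \quad
#'       \text{s.t. } \sum_{p \ni e} x_p \ge 1 \ (\text{or} = 1) \ \forall e,}
#' with one binary indicator per candidate path, roughness costs under the
#' configured measure, and one covering row per graph edge (inequality for
#' overlapping covers, equality for exact covers).
#'
#' @param candidates a `candidate_paths` object
#' @param graph a [filament_graph()]
#' @param options a [cover_options()]
#' @return object of class `cover_program`: costs, per-path edge indices,
#'   per-edge path indices, the paths themselves, and the cover mode.
#' @export
build_cover_program <- function(candidates, graph, options = cover_options()) {
  paths <- candidates$paths
  stopifnot(length(paths) > 0)
  path_edges <- lapply(paths, function(p) path_edge_ids(graph, p))
  costs <- costs_from_weights(path_edges, graph$edges$weight,
                              options$roughness, options$all_variant)
  stopifnot(all(is.finite(costs)), all(costs >= 0))
  E <- n_edges(graph)
  edge_paths <- vector("list", E)
  for (j in seq_along(path_edges)) {
    for (e in path_edges[[j]]) edge_paths[[e]] <- c(edge_paths[[e]], j)
  }
  empty <- vapply(edge_paths, is.null, logical(1))
  if (any(empty)) {
    i <- which(empty)[1]
    stop(sprintf("infeasible: edge %d--%d covered by no candidate path",
                 graph$edges$from[i], graph$edges$to[i]), call. = FALSE)
  }
  structure(
    list(costs = costs, path_edges = path_edges, edge_paths = edge_paths,
         paths = paths, n_edges = E, exact = (options$cover == "exact"),
         options = options, graph = graph),
    class = "cover_program"
  )
}

# roughness costs from ordered per-path edge indices and a weight vector;
# shared between program construction and weight-only re-solves (noise
# protocol), where topology and candidate set are fixed
costs_from_weights <- function(path_edges, weights, measure,
                               all_variant = "per_edge_max") {
  vapply(path_edges, function(eids) {
    w <- weights[eids]
    if (length(w) == 1L) return(w)
    if (measure == "pair") return(mean(abs(diff(w))))
    if (all_variant == "range") return(max(w) - min(w))
    mean(pmax(w - min(w), max(w) - w))
  }, numeric(1))
}

#' @export
print.cover_program <- function(x, ...) {
  cat(sprintf("<cover_program> %d path variables, %d covering rows (%s)\n",
              length(x$costs), x$n_edges,
              if (x$exact) "equalities" else ">= 1"))
  invisible(x)
}

# ---- exact branch-and-bound for the binary covering subproblem -------------
#
# Minimise sum(costs[sel]) subject to: every edge covered >= 1 (exact: == 1,
# i.e. selected paths pairwise edge-disjoint). Costs may be negative (they
# are during Dinkelbach iterations). Strategy:
#   * overlapping mode: paths with negative cost are always part of an
#     optimum (they lower the objective and can only help coverage), so
#     they are fixed upfront, leaving non-negative costs for the search;
#   * the remaining program splits into independent blocks: two edges
#     interact only if some candidate path contains both, and on
#     filamentous graphs candidate paths rarely bridge filaments, so the
#     blocks are small and their optima add up;
#   * per block: greedy incumbent, then depth-first branch-and-bound on the
#     uncovered edge with the fewest covering paths, inclusion/exclusion
#     branching, pruned with an incrementally maintained bound
#     sum_{e uncovered} min_{p containing e} costs[p]/|p|
#     (a valid lower bound since any cover charges every uncovered edge at
#     least its cheapest per-edge cost share).

solve_cover_bnb <- function(costs, path_edges, edge_paths, n_edge, exact) {
  np <- length(costs)
  forced <- integer(0)
  covered0 <- logical(n_edge)
  if (!exact && any(costs < 0)) {
    forced <- which(costs < 0)
    for (j in forced) covered0[path_edges[[j]]] <- TRUE
  }
  remaining <- which(!covered0)
  if (length(remaining) == 0L) {
    return(list(selected = forced, objective = sum(costs[forced])))
  }

  ratio <- costs / lengths(path_edges)
  ep_sorted <- lapply(edge_paths, function(js) js[order(costs[js])])

  # independent blocks: connected components of the edge/path incidence
  comp <- integer(n_edge)
  ncomp <- 0L
  for (e0 in remaining) {
    if (comp[e0] != 0L) next
    ncomp <- ncomp + 1L
    queue <- e0
    comp[e0] <- ncomp
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (j in edge_paths[[cur]]) {
        for (e2 in path_edges[[j]]) {
          if (!covered0[e2] && comp[e2] == 0L) {
            comp[e2] <- ncomp
            queue <- c(queue, e2)
          }
        }
      }
    }
  }

  sel_all <- forced
  for (ci in seq_len(ncomp)) {
    res <- bnb_block(which(comp == ci), costs, path_edges, ep_sorted,
                     ratio, exact, n_edge)
    if (is.null(res)) {
      stop("solver error: covering program infeasible", call. = FALSE)
    }
    sel_all <- c(sel_all, res)
  }
  sel_all <- sort(unique(sel_all))
  list(selected = sel_all, objective = sum(costs[sel_all]))
}

# branch-and-bound over one independent block of uncovered edges
bnb_block <- function(edges_c, costs, path_edges, ep_sorted, ratio,
                      exact, n_edge) {
  in_block <- logical(n_edge)
  in_block[edges_c] <- TRUE
  min_ratio <- vapply(edges_c, function(e) min(ratio[ep_sorted[[e]]]),
                      numeric(1))
  names(min_ratio) <- NULL
  mr <- numeric(n_edge)
  mr[edges_c] <- min_ratio
  ncand_static <- integer(n_edge)
  ncand_static[edges_c] <- lengths(ep_sorted)[edges_c]
  eps <- 1e-12

  # dual-ascent prices: raise y_e edge by edge, keeping sum_{e in p} y_e <=
  # costs[p] for every path; for any subset U of block edges, sum_{e in U}
  # y_e is then a lower bound on the cost of covering U, so the prices give
  # a second, usually much tighter, incremental node bound. Only valid with
  # non-negative costs (y >= 0 cannot be dual-feasible against a
  # negative-cost path), so the prices stay zero for blocks that still
  # contain negative costs -- the exact-cover case of the ratio iteration,
  # where the ratio bound alone carries the pruning.
  block_paths <- sort(unique(unlist(ep_sorted[edges_c])))
  use_prices <- all(costs[block_paths] >= 0)
  pidx <- integer(length(costs))
  pidx[block_paths] <- seq_along(block_paths)
  ascend <- function(edge_order) {
    y <- numeric(n_edge)
    slack <- costs[block_paths]
    for (e in edge_order) {
      js <- pidx[ep_sorted[[e]]]
      m <- min(slack[js])
      if (m > 0) {
        y[e] <- m
        slack[js] <- slack[js] - m
      }
    }
    y
  }
  if (use_prices) {
    # several deterministic ascent orders: different orders are tight on
    # different edge subsets, and the node bound takes the best of them
    orders <- list(
      edges_c[order(ncand_static[edges_c])],
      edges_c[order(-ncand_static[edges_c])],
      edges_c[order(mr[edges_c])],
      edges_c[order(-mr[edges_c])]
    )
    Y <- vapply(orders, ascend, numeric(n_edge))
  } else {
    Y <- matrix(0, nrow = n_edge, ncol = 1L)
  }

  # greedy incumbent restricted to the block
  greedy <- function() {
    covered <- !in_block
    blocked <- logical(length(block_paths))
    uncov_cnt <- vapply(block_paths, function(j) {
      sum(!covered[path_edges[[j]]])
    }, integer(1))
    sel <- integer(0)
    tot <- 0
    while (any(!covered[edges_c])) {
      ok <- uncov_cnt > 0L & !blocked
      if (!any(ok)) return(NULL)
      score <- ifelse(ok, costs[block_paths] / pmax(uncov_cnt, 1L), Inf)
      ties <- which(score <= min(score) + 1e-15)
      jj <- ties[which.max(uncov_cnt[ties])] # prefer coverage on cost ties
      j <- block_paths[jj]
      sel <- c(sel, j)
      tot <- tot + costs[j]
      newly <- path_edges[[j]][!covered[path_edges[[j]]]]
      covered[path_edges[[j]]] <- TRUE
      for (e in newly) {
        hit <- match(ep_sorted[[e]], block_paths)
        hit <- hit[!is.na(hit)]
        uncov_cnt[hit] <- uncov_cnt[hit] - 1L
      }
      if (exact) {
        for (e in path_edges[[j]]) {
          hit <- match(ep_sorted[[e]], block_paths)
          blocked[hit[!is.na(hit)]] <- TRUE
        }
      }
    }
    list(sel = sel, cost = tot)
  }
  g <- greedy()
  best_cost <- if (is.null(g)) Inf else g$cost
  best_sel <- if (is.null(g)) NULL else g$sel

  n_uncov0 <- length(edges_c)
  lb0 <- sum(min_ratio)
  # a zero price sum would wrongly assert "remaining cost >= 0" when
  # negative costs are present, so the disabled price bound is -Inf
  lby0 <- if (use_prices) colSums(Y[edges_c, , drop = FALSE]) else -Inf

  # reduced-cost fixing: with dual-feasible prices y, any cover containing
  # path p costs at least sum(y) + (costs[p] - sum_{e in p} y_e); paths for
  # which that exceeds the incumbent can never be optimal and are dropped
  fixed_out <- logical(length(costs))
  if (use_prices && is.finite(best_cost)) {
    k_best <- which.max(lby0)
    ybest <- Y[, k_best]
    lb_root <- lby0[k_best]
    rc <- vapply(block_paths, function(j) {
      costs[j] - sum(ybest[path_edges[[j]]])
    }, numeric(1))
    fixed_out[block_paths[lb_root + rc > best_cost + 1e-9]] <- TRUE
    fixed_out[best_sel] <- FALSE # the incumbent itself always stays
  }

  recurse <- function(sel, cost, lb, lby, banned, covered, used_edge,
                      n_uncov) {
    if (n_uncov == 0L) {
      if (cost < best_cost - eps) {
        best_cost <<- cost
        best_sel <<- sel
      }
      return(invisible(NULL))
    }
    if (cost + max(lb, max(lby)) >= best_cost - eps) return(invisible(NULL))
    # branch on the uncovered block edge with the fewest covering paths
    unc <- edges_c[!covered[edges_c]]
    e_branch <- unc[which.min(ncand_static[unc])]
    js <- ep_sorted[[e_branch]]
    js <- js[!banned[js]]
    if (exact && length(js) > 0L) {
      keep <- vapply(js, function(j) !any(used_edge[path_edges[[j]]]),
                     logical(1))
      js <- js[keep]
    }
    for (j in js) {
      # candidates are cost-sorted: once a path alone busts the incumbent,
      # no later candidate can help either -- but only when no negative
      # (ratio-shifted) costs remain, since those may pay off later
      if (use_prices && cost + costs[j] >= best_cost - eps) break
      ej <- path_edges[[j]]
      newly <- ej[!covered[ej] & in_block[ej]]
      lb_child <- lb - sum(mr[newly])
      lby_child <- lby - colSums(Y[newly, , drop = FALSE])
      if (cost + costs[j] + max(lb_child, max(lby_child)) <
            best_cost - eps) {
        cc <- covered
        cc[ej] <- TRUE
        ue <- used_edge
        if (exact) ue[ej] <- TRUE
        recurse(c(sel, j), cost + costs[j], lb_child, lby_child, banned,
                cc, ue, n_uncov - length(newly))
      }
      banned[j] <- TRUE
    }
    invisible(NULL)
  }

  covered_init <- !in_block
  recurse(integer(0), 0, lb0, lby0, fixed_out, covered_init,
          used_edge = logical(n_edge), n_uncov = n_uncov0)
  best_sel
}

# assemble a filament_cover from selected program variables
cover_from_selection <- function(program, sel, objective = NULL) {
  paths <- program$paths[sel]
  cov <- filament_cover(paths, program$graph, options = program$options,
                        check = TRUE)
  cov$total_roughness <- cover_roughness(
    cov, program$graph, measure = program$options$roughness,
    objective = "total", all_variant = program$options$all_variant
  )
  cov
}

#' Solve the covering program for minimal total roughness
#'
#' Exact branch-and-bound over the binary covering program; the returned
#' selection attains the minimum total roughness over the candidate set.
#'
#' @param program a `cover_program` from [build_cover_program()]
#' @return a [filament_cover()]; its `total_roughness` equals the objective.
#' @export
solve_total <- function(program) {
  res <- solve_cover_bnb(program$costs, program$path_edges,
                         program$edge_paths, program$n_edges, program$exact)
  cover_from_selection(program, res$selected)
}

#' Solve the covering program for minimal average roughness
#'
#' Minimises the ratio (sum of selected costs)/(number selected) by
#' Dinkelbach iteration: repeatedly solve the parametric binary subproblem
#' `min sum (r_p - lambda) x_p` under the covering constraints and update
#' `lambda` to the incumbent ratio; stop when the parametric optimum is
#' `>= -tol`. Dinkelbach is exact and finite for ratio objectives with a
#' positive denominator, so the returned cover attains the minimum average
#' roughness over the candidate set. The iteration starts from the ratio of
#' the all-singletons cover, which is always feasible.
#'
#' @param program a `cover_program`
#' @param tol convergence tolerance on the parametric objective
#' @param max_iter iteration cap; non-convergence raises a solver error
#'   reporting the last `lambda`.
#' @return a [filament_cover()] with attribute `average_roughness`.
#' @export
solve_average <- function(program, tol = 1e-9, max_iter = 100L) {
  singles <- which(lengths(program$path_edges) == 1L)
  if (length(singles) < program$n_edges) {
    # fall back to a greedy feasible ratio if singletons are not all present
    res0 <- solve_cover_bnb(program$costs, program$path_edges,
                            program$edge_paths, program$n_edges,
                            program$exact)
    lambda <- res0$objective / length(res0$selected)
  } else {
    lambda <- mean(program$costs[singles])
  }
  for (it in seq_len(max_iter)) {
    res <- solve_cover_bnb(program$costs - lambda, program$path_edges,
                           program$edge_paths, program$n_edges,
                           program$exact)
    f <- res$objective
    if (f >= -tol) {
      # F(lambda) <= 0 always holds at a feasible ratio, so the current
      # minimiser attains a ratio within tol of the optimum
      sel <- res$selected
      cov <- cover_from_selection(program, sel)
      attr(cov, "average_roughness") <- cov$total_roughness / length(sel)
      attr(cov, "dinkelbach_iterations") <- it
      return(cov)
    }
    new_lambda <- sum(program$costs[res$selected]) / length(res$selected)
    if (new_lambda > lambda + 1e-9) {
      stop("solver error: Dinkelbach ratio increased, last lambda = ",
           lambda, call. = FALSE)
    }
    lambda <- new_lambda
  }
  stop("solver error: Dinkelbach did not converge, last lambda = ", lambda,
       call. = FALSE)
}

#' Decompose a graph into filaments by solving the filament cover problem
#'
#' End-to-end orchestration: sample candidate paths according to the
#' options, score them with the configured roughness measure, build the
#' covering program, and solve it for the total or average objective. The
#' result is deterministic given `options$seed`.
#'
#' @param graph a [filament_graph()]
#' @param options a [cover_options()]
#' @return a [filament_cover()]; attribute `n_candidates` records the size
#'   of the sampled path set.
#' @examples
#' g <- filament_graph(
#'   nodes = data.frame(id = 0:3, x = 0:3, y = c(0, 0, 0, 0)),
#'   edges = data.frame(from = 0:2, to = 1:3, weight = c(0.5, 0.5, 0.5))
#' )
#' solve_fcp(g) # one straight filament of zero roughness
#' @export
solve_fcp <- function(graph, options = cover_options()) {
  candidates <- sample_paths(graph, options)
  program <- build_cover_program(candidates, graph, options)
  cov <- if (options$objective == "total") solve_total(program)
         else solve_average(program)
  attr(cov, "n_candidates") <- length(candidates$paths)
  cov
}
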