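test_that("program construction counts variables and rows correctly", {
  g <- chain_graph(rep(0.5, 3))
  cand <- sample_paths_bfs(g)
  prog <- build_cover_program(cand, g, cover_options())
  expect_equal(length(prog$costs), 6)
  expect_equal(prog$n_edges, 3)
  expect_false(prog$exact)
  prog_e <- build_cover_program(cand, g, cover_options(cover = "exact"))
  expect_true(prog_e$exact)

  # an edge no candidate covers is an infeasibility error naming the edge
  cand_bad <- structure(list(paths = list(c(0L, 1L)), provenance = "BFS",
                             includes_singletons = FALSE),
                        class = "candidate_paths")
  expect_error(build_cover_program(cand_bad, g, cover_options()),
               "infeasible: edge 1--2")
})

test_that("a zero-roughness straight chain is covered by one filament", {
  g <- chain_graph(rep(0.5, 4))
  for (cover in c("over", "exact")) {
    sol <- solve_fcp(g, cover_options("bfs", cover, "pair", "total"))
    expect_equal(length(sol$paths), 1)
    expect_equal(sol$total_roughness, 0)
  }
})

test_that("the X-crossing resolves into weight-consistent filaments", {
  g <- x_graph(w_horizontal = 0.8, w_vertical = 0.3)
  # crossing at 90 degrees: BFS candidates cannot mix the two filaments,
  # so solve with a hand-built candidate set that includes mixed pairings
  mixed <- structure(list(paths = list(
    c(0L, 2L, 1L), c(3L, 2L, 4L),   # straight filaments
    c(0L, 2L, 4L), c(3L, 2L, 1L),   # mixed pairings
    c(0L, 2L), c(2L, 1L), c(2L, 3L), c(2L, 4L)
  ), provenance = "BFS", includes_singletons = TRUE),
  class = "candidate_paths")
  prog <- build_cover_program(mixed, g, cover_options(cover = "exact"))
  sol <- solve_total(prog)
  expect_equal(sol$total_roughness, 0) # never the mixed pairing (R = 0.5)
  sel <- lapply(sol$paths, canonicalize_path)
  expect_setequal(lapply(sel, paste, collapse = ","),
                  list("0,2,1", "3,2,4"))
})

test_that("solver matches exhaustive enumeration on tiny programs", {
  n_checked <- 0
  for (seed in 1:30) {
    g <- random_tiny_graph(seed, n_nodes = 5L, max_edges = 7L)
    cand <- tiny_candidates(g, seed, max_paths = 12L)
    for (cover in c("over", "exact")) {
      opt <- cover_options(cover = cover)
      prog <- build_cover_program(cand, g, opt)
      oracle <- brute_force_optimum(prog)
      sol_t <- solve_total(prog)
      expect_equal(sol_t$total_roughness, oracle$total, tolerance = 1e-9)
      sol_a <- solve_average(prog)
      expect_equal(attr(sol_a, "average_roughness"), oracle$average,
                   tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 60)
})

test_that("returned covers satisfy their constraints independently of the solver", {
  sc <- contrived_scene(seed = 5)
  for (cover in c("over", "exact")) {
    sol <- solve_fcp(sc$graph, cover_options("bfs", cover, "pair", "total"))
    labels <- edge_cover_labels(sol, sc$graph) # errors if any edge uncovered
    counts <- lengths(labels)
    expect_true(all(counts >= 1))
    if (cover == "exact") expect_true(all(counts == 1))
  }
})

test_that("average-optimal covers dominate total-optimal covers on average", {
  for (seed in c(2, 9, 17)) {
    g <- random_tiny_graph(seed, n_nodes = 6L, max_edges = 8L)
    cand <- tiny_candidates(g, seed, max_paths = 14L)
    prog <- build_cover_program(cand, g, cover_options())
    sol_t <- solve_total(prog)
    sol_a <- solve_average(prog)
    avg_t <- sol_t$total_roughness / length(sol_t$paths)
    expect_lte(attr(sol_a, "average_roughness"), avg_t + 1e-9)
    # and symmetrically for the total objective
    expect_lte(sol_t$total_roughness, sol_a$total_roughness + 1e-9)
  }
})

test_that("equal costs reduce the average objective to minimum cardinality", {
  g <- chain_graph(rep(0.5, 3))
  cand <- structure(list(paths = list(
    c(0L, 1L), c(1L, 2L), c(2L, 3L), c(0L, 1L, 2L), c(1L, 2L, 3L)
  ), provenance = "BFS", includes_singletons = TRUE),
  class = "candidate_paths")
  prog <- build_cover_program(cand, g, cover_options())
  prog$costs <- rep(0.4, 5) # force equal path costs: ratio is constant
  sol <- solve_average(prog)
  expect_equal(length(sol$paths), 2) # so only the cardinality can shrink
})

test_that("solving is deterministic given the options seed", {
  sc <- contrived_scene(seed = 2)
  opt <- cover_options("rmst", "over", "pair", "total", n_trees = 5,
                       seed = 123)
  a <- solve_fcp(sc$graph, opt)
  b <- solve_fcp(sc$graph, opt)
  expect_identical(a$paths, b$paths)
  expect_identical(a$total_roughness, b$total_roughness)
})
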