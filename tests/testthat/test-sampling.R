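test_that("canonicalisation picks one representative per orbit", {
  expect_equal(canonicalize_path(c(3L, 2L, 1L)), c(1L, 2L, 3L))
  expect_equal(canonicalize_path(c(1L, 2L, 3L)), c(1L, 2L, 3L))
  # loop: enumerate the rotation/reversal orbit by hand
  expect_equal(canonicalize_path(c(2L, 5L, 4L, 2L)), c(2L, 4L, 5L, 2L))
  # idempotence on open and closed paths
  for (p in list(c(1L, 2L, 3L), c(2L, 4L, 5L, 2L), c(0L, 7L))) {
    expect_identical(canonicalize_path(canonicalize_path(p)),
                     canonicalize_path(p))
  }
})

test_that("BFS enumerates exactly the admissible paths of a straight chain", {
  g <- chain_graph(rep(0.5, 3)) # 4-node straight chain
  ps <- sample_paths_bfs(g)
  expect_equal(length(ps$paths), 6) # 3 singletons + 2 two-edge + 1 three-edge
  lens <- sort(vapply(ps$paths, function(p) length(p) - 1L, integer(1)))
  expect_equal(lens, c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("BFS prunes bends at or beyond the straightness threshold", {
  ps <- sample_paths_bfs(l_graph()) # 90 degree bend >= 60
  expect_equal(length(ps$paths), 2) # only the two singletons
  # with a tolerant threshold the bent path is admitted
  ps2 <- sample_paths_bfs(l_graph(), angle_max_deg = 91)
  expect_equal(length(ps2$paths), 3)
})

test_that("BFS detects closed loops including the seam deflection", {
  g <- polygon_graph(k = 8) # deflections 45 < 60 everywhere incl. seam
  ps <- sample_paths_bfs(g)
  closed <- Filter(function(p) p[1] == p[length(p)] && length(p) > 3,
                   ps$paths)
  expect_equal(length(closed), 1)
  expect_equal(length(closed[[1]]) - 1L, 8) # the full octagon
  # squares bend at 90: no closed path
  g4 <- polygon_graph(k = 4)
  ps4 <- sample_paths_bfs(g4)
  expect_true(all(vapply(ps4$paths, function(p) p[1] != p[length(p)],
                         logical(1))))
})

test_that("every sampled BFS path satisfies the angle criterion", {
  g <- contrived_scene(seed = 3)$graph
  ps <- sample_paths_bfs(g, angle_max_deg = 60)
  defl <- vapply(ps$paths, max_deflection_angle, numeric(1), graph = g)
  expect_true(all(defl < 60))
  # canonical closure: stored paths are fixed points of canonicalisation
  expect_true(all(vapply(ps$paths, function(p) {
    identical(canonicalize_path(p), p)
  }, logical(1))))
})

test_that("BFS respects the safety cap with an explicit resource error", {
  g <- contrived_scene(seed = 1)$graph
  expect_error(sample_paths_bfs(g, max_paths = 10), "resource error")
})

test_that("RMST sampling covers trees exactly and loops never fully", {
  # tree input: one repetition already yields all N(N-1)/2 paths
  g <- chain_graph(rep(0.5, 4)) # path graph = its own spanning tree
  ps <- sample_paths_rmst(g, n_trees = 1, seed = 1)
  expect_equal(length(ps$paths), 5 * 4 / 2)
  ps_many <- sample_paths_rmst(g, n_trees = 5, seed = 2)
  expect_equal(length(ps_many$paths), length(ps$paths))

  # cycle: trees are loopless, so no candidate contains all edges
  g4 <- polygon_graph(k = 4)
  ps4 <- sample_paths_rmst(g4, n_trees = 30, seed = 3)
  n_edges_per_path <- vapply(ps4$paths, function(p) length(p) - 1L,
                             integer(1))
  expect_true(all(n_edges_per_path <= 3))

  # determinism
  a <- sample_paths_rmst(g4, n_trees = 10, seed = 99)
  b <- sample_paths_rmst(g4, n_trees = 10, seed = 99)
  expect_identical(a$paths, b$paths)
})

test_that("singletons are always included, guaranteeing coverage", {
  for (seed in 1:5) {
    g <- random_tiny_graph(seed, n_nodes = 6L, max_edges = 8L)
    for (ps in list(sample_paths_bfs(g),
                    sample_paths_rmst(g, n_trees = 3, seed = seed))) {
      covered <- unique(unlist(lapply(ps$paths, function(p) {
        filamentcover:::path_edge_ids(g, p)
      })))
      expect_setequal(covered, seq_len(nrow(g$edges)))
    }
  }
})
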