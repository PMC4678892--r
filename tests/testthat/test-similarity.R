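test_that("edge distance follows the at-most-d-nodes convention", {
  g <- chain_graph(rep(0.5, 3)) # edges 1:(0-1), 2:(1-2), 3:(2-3)
  expect_equal(edge_distance(g, 1, 2), 0) # share node 1
  expect_equal(edge_distance(g, 1, 1), 0)
  expect_equal(edge_distance(g, 1, 3), 1) # chain a-b-c-d
  # disconnected pair
  g2 <- filament_graph(
    nodes = data.frame(id = 0:3, x = c(0, 1, 5, 6), y = 0),
    edges = data.frame(from = c(0, 2), to = c(1, 3), weight = 1)
  )
  expect_equal(edge_distance(g2, 1, 2), Inf)
})

test_that("contingency counts reproduce hand-enumerated tables", {
  g <- chain_graph(rep(0.5, 3))
  one <- filament_cover(list(0:3), g)
  singles <- filament_cover(list(c(0L, 1L), c(1L, 2L), c(2L, 3L)), g)
  h <- contingency_counts(one, singles, g, d = 1)
  expect_equal(c(h$ss, h$sd, h$ds, h$dd), c(0, 2, 0, 0))
  expect_equal(rand_index(h), 0)
  expect_equal(jaccard_index(h), 0)

  # identical labellings never disagree
  h_same <- contingency_counts(one, one, g, d = 1)
  expect_equal(h_same$sd + h_same$ds, 0)
  expect_equal(rand_index(h_same), 1)
  expect_equal(jaccard_index(h_same), 1)

  # d = Inf admits all n(n-1)/2 pairs
  h_inf <- contingency_counts(one, singles, g, d = Inf)
  expect_equal(h_inf$ss + h_inf$sd + h_inf$ds + h_inf$dd, 3)

  # five-edge chain, hand enumeration at d = 2:
  # A groups {e1,e2,e3} and {e4,e5}; B groups {e1,e2} and {e3,e4,e5}
  g5 <- chain_graph(rep(0.5, 5))
  A <- filament_cover(list(0:3, 3:5), g5)
  B <- filament_cover(list(0:2, 2:5), g5)
  # admissible pairs at d=2 (edge distance <= 1): (1,2),(1,3),(2,3),(2,4),
  # (3,4),(3,5),(4,5)
  # A-same: 12,13,23,45; B-same: 12,34,35,45
  h2 <- contingency_counts(A, B, g5, d = 2)
  expect_equal(c(h2$ss, h2$sd, h2$ds, h2$dd), c(2, 2, 2, 1))

  short_labels <- structure(list(0L, 0L), class = "edge_cover_labels")
  expect_error(contingency_counts(one, short_labels, g, d = 1),
               "consistency error")
})

test_that("structure-aware indices at d = Inf equal the classical indices", {
  for (seed in 1:20) {
    g <- random_tiny_graph(seed, n_nodes = 7L, max_edges = 12L)
    A <- random_labels(g, seed * 2 + 1)
    B <- random_labels(g, seed * 2 + 2)
    h <- contingency_counts(A, B, g, d = Inf)
    oracle <- classical_indices(A, B)
    expect_equal(rand_index(h), oracle$RI)
    ji <- jaccard_index(h)
    if (is.nan(oracle$JI)) expect_true(is.nan(ji))
    else expect_equal(ji, oracle$JI)
  }
})

test_that("similarity measures are symmetric and relabelling-invariant", {
  for (seed in 1:10) {
    g <- random_tiny_graph(seed + 100, n_nodes = 6L, max_edges = 10L)
    A <- random_labels(g, seed * 3 + 1)
    B <- random_labels(g, seed * 3 + 2)
    for (d in c(1, 2, Inf)) {
      hab <- contingency_counts(A, B, g, d = d)
      hba <- contingency_counts(B, A, g, d = d)
      expect_equal(rand_index(hab), rand_index(hba))
      expect_equal(jaccard_index(hab), jaccard_index(hba))
    }
    # relabelling: permute the ids of A
    perm <- sample(100:200)
    A_perm <- structure(lapply(A, function(v) perm[v + 1L]),
                        class = "edge_cover_labels")
    h1 <- contingency_counts(A, B, g, d = 1)
    h2 <- contingency_counts(A_perm, B, g, d = 1)
    expect_identical(c(h1$ss, h1$sd, h1$ds, h1$dd),
                     c(h2$ss, h2$sd, h2$ds, h2$dd))
  }
})

test_that("admissible pair totals grow with d and saturate at the diameter", {
  g <- random_tiny_graph(7, n_nodes = 7L, max_edges = 10L)
  A <- random_labels(g, 1)
  B <- random_labels(g, 2)
  totals <- vapply(c(1, 2, 3, 5, 10, Inf), function(d) {
    h <- contingency_counts(A, B, g, d = d)
    h$ss + h$sd + h$ds + h$dd
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  # beyond the edge-distance diameter the indices equal the classical ones
  h_big <- contingency_counts(A, B, g, d = 50)
  h_inf <- contingency_counts(A, B, g, d = Inf)
  expect_equal(rand_index(h_big), rand_index(h_inf))
  expect_equal(jaccard_index(h_big), jaccard_index(h_inf))
})

test_that("variation of information handles the partition cases", {
  g4 <- chain_graph(rep(0.5, 4))
  one <- filament_cover(list(0:4), g4)
  expect_equal(variation_of_information(one, one, g4), 0)
  halves <- filament_cover(list(0:2, 2:4), g4)
  expect_equal(variation_of_information(one, halves, g4), log(2))
  # overlap: domain error
  over <- filament_cover(list(0:4, c(1L, 2L)), g4)
  expect_error(variation_of_information(over, one, g4),
               "overlapping partitions")
  # invariant under swapping
  expect_equal(variation_of_information(halves, one, g4), log(2))
})

test_that("filament matching maximises shared edges", {
  g <- chain_graph(rep(0.5, 6))
  A <- filament_cover(list(0:3, 3:6), g)
  m_id <- match_filaments(A, A, g)
  expect_equal(m_id$b_id, m_id$a_id)
  expect_equal(attr(m_id, "total_shared"), 6)

  # shared-edge matrix [[3,1],[0,2]]: identity matching (value 5) beats the
  # swap (value 1)
  B <- filament_cover(list(0:4, 4:6), g)
  m <- match_filaments(A, B, g)
  expect_equal(m$b_id, c(0L, 1L))
  expect_equal(attr(m, "total_shared"), 5)

  # rectangular: surplus filaments stay unmatched
  C <- filament_cover(list(0:2, c(2L, 3L), 3:6), g)
  m2 <- match_filaments(C, A, g)
  expect_equal(sum(is.na(m2$b_id)), 1)
})
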