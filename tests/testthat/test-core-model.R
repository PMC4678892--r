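test_that("graph construction enforces the model invariants", {
  g <- chain_graph(c(0.5, 0.5))
  expect_s3_class(g, "filament_graph")
  expect_equal(nrow(g$edges), 2)

  nodes <- data.frame(id = 0:1, x = 0:1, y = c(0, 0))
  expect_error(
    filament_graph(nodes, data.frame(from = 0, to = 0, weight = 1)),
    "self-loop"
  )
  expect_error(
    filament_graph(nodes, data.frame(from = c(0, 1), to = c(1, 0),
                                     weight = c(1, 1))),
    "parallel"
  )
  expect_error(
    filament_graph(nodes, data.frame(from = 0, to = 1, weight = -0.1)),
    "weight"
  )
  expect_error(
    filament_graph(nodes, data.frame(from = 0, to = 5, weight = 1)),
    "unknown node"
  )
  expect_error(
    filament_graph(data.frame(id = 0:1, x = c(0, NA), y = c(0, 0)),
                   data.frame(from = 0, to = 1, weight = 1)),
    "coordinate"
  )
})

test_that("minimal GML reads correctly in both coordinate dialects", {
  top <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    "  node [ id 0 x 0.0 y 0.0 ]",
    "  node [ id 1 x 1.0 y 0.0 ]",
    "  edge [ source 0 target 1 weight 0.5 ]",
    "]"
  ), top)
  g <- read_gml(top)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 0.5)

  nested <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    "  node [ id 0 graphics [ x 0.0 y 0.0 ] ]",
    "  node [ id 1 graphics [ x 1.0 y 0.0 ] ]",
    "  edge [ source 0 target 1 weight 0.5 ]",
    "]"
  ), nested)
  g2 <- read_gml(nested)
  expect_equal(g2$nodes$x, g$nodes$x)
  expect_equal(g2$edges$weight, 0.5)
})

test_that("malformed GML raises the documented errors", {
  f <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    "  node [ id 0 x 0 y 0 ]",
    "  node [ id 1 x 1 y 0 ]",
    "  edge [ source 0 target 1 ]",
    "]"
  ), f)
  expect_error(read_gml(f), "weight")

  f2 <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    "  node [ id 0 y 0 ]",
    "  node [ id 1 x 1 y 0 ]",
    "  edge [ source 0 target 1 weight 1 ]",
    "]"
  ), f2)
  expect_error(read_gml(f2), "coordinates")

  expect_error(read_gml(tempfile()), "no such file")
})

test_that("write/read round-trip preserves topology, positions and weights", {
  set.seed(42)
  g <- random_tiny_graph(seed = 42, n_nodes = 8L, max_edges = 10L)
  f <- tempfile(fileext = ".gml")
  write_cover_gml(g, NULL, f)
  g2 <- read_gml(f)
  expect_equal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$nodes$x, signif(g$nodes$x, 6), tolerance = 1e-6)
  expect_equal(g2$nodes$y, signif(g$nodes$y, 6), tolerance = 1e-6)
  expect_equal(g2$edges$from, g$edges$from)
  expect_equal(g2$edges$to, g$edges$to)
  expect_equal(g2$edges$weight, signif(g$edges$weight, 6), tolerance = 1e-6)
})

test_that("cover GML stores sorted filament ids and the colour key", {
  g <- chain_graph(c(0.4, 0.4, 0.4))
  cov <- filament_cover(list(c(0L, 1L, 2L, 3L), c(1L, 2L)), g)
  f <- tempfile(fileext = ".gml")
  write_cover_gml(g, cov, f)
  txt <- readLines(f)
  expect_true(any(grepl('filaments "0;1"', txt)))
  expect_true(any(grepl('^\\s+filament 0$', txt)))
  # round-trip of the labelling
  g2 <- read_gml(f)
  labels <- labels_from_gml_graph(g2)
  expect_equal(labels[[2]], c(0L, 1L))
  expect_equal(labels[[1]], 0L)

  # exact cover: exactly one id per edge
  cov_exact <- filament_cover(list(c(0L, 1L, 2L, 3L)), g)
  write_cover_gml(g, cov_exact, f)
  labels2 <- labels_from_gml_graph(read_gml(f))
  expect_true(all(lengths(labels2) == 1))

  # cover referencing an edge absent from the graph
  g_small <- chain_graph(c(0.4, 0.4))
  expect_error(write_cover_gml(g_small, cov, f), "consistency error")
})

test_that("filament CSV has the fixed schema and is byte-stable", {
  g <- chain_graph(0.4) # one edge of length 1... use 2-unit edge below
  g2 <- filament_graph(
    nodes = data.frame(id = 0:1, x = c(0, 2), y = c(0, 0)),
    edges = data.frame(from = 0, to = 1, weight = 0.4)
  )
  cov <- filament_cover(list(c(0L, 1L)), g2)
  m <- filament_metrics(cov, g2)
  expect_equal(m$n_edges, 1L)
  expect_equal(m$length_geometric, 2)
  expect_equal(m$roughness_pair, 0.4) # single-edge rule
  expect_equal(m$convolutedness, 1)

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_filament_csv(m, f1)
  write_filament_csv(m, f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1)[1]
  expect_identical(header,
    "filament_id,n_edges,length_geometric,mean_weight,roughness_pair,roughness_all,max_angle_deg,median_orientation_deg,convolutedness,node_sequence")

  expect_error(write_filament_csv(m[0, ], tempfile()), "at least one")
})
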