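test_that("a straight segment yields 2 endpoints and 1 edge", {
  m <- matrix(FALSE, 20, 60); m[10, 5:55] <- TRUE
  g <- skeleton_to_graph(m)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(sort(g$nodes$kind), c("endpoint", "endpoint"))
  expect_equal(n_edges(g), 1L)
  e <- g$edges[[1]]
  # path endpoints coincide with node coordinates
  ends <- rbind(e$path[1, ], e$path[nrow(e$path), ])
  nodes <- as.matrix(g$nodes[, c("row", "col")])
  expect_true(all(apply(ends, 1, function(p) {
    any(p[1] == nodes[, 1] & p[2] == nodes[, 2])
  })))
  # path is 8-connected
  d <- abs(diff(e$path))
  expect_true(all(pmax(d[, 1], d[, 2]) == 1))
})

test_that("a cross yields one junction, four endpoints, four edges", {
  g <- skeleton_to_graph(cross_mask(41))
  expect_equal(n_edges(g), 4L)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)
})

test_that("empty skeletons and isolated cycles are handled", {
  g <- skeleton_to_graph(matrix(FALSE, 10, 10))
  expect_equal(nrow(g$nodes), 0L)
  expect_equal(n_edges(g), 0L)
  ring <- skeletonize(annulus_mask())
  g <- skeleton_to_graph(ring)
  expect_equal(n_edges(g), 1L)
  e <- g$edges[[1]]
  expect_equal(e$a, e$b)                    # self-loop
  expect_gt(nrow(e$path), 20)
})

test_that("short terminal spurs are pruned, long branches are kept", {
  m <- matrix(FALSE, 40, 80)
  m[20, 5:75] <- TRUE          # main line
  m[17:19, 40] <- TRUE         # 3-px spur
  g <- skeleton_to_graph(m)
  expect_equal(n_edges(g), 1L)                 # spur removed
  m[10:19, 60] <- TRUE         # 10-px branch survives
  g <- skeleton_to_graph(m)
  expect_equal(n_edges(g), 3L)
})

test_that("no edge shorter than the minimum survives pruning", {
  for (s in 1:5) {
    ph <- generate_phantom(seed = 600 + s, size = 96, n_trees = 2)
    g <- skeleton_to_graph(skeletonize(ph$mask))
    if (n_edges(g) > 0) {
      lens <- vapply(g$edges, function(e) nrow(e$path), integer(1))
      expect_true(all(lens >= 3))
    }
  }
})
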