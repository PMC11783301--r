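test_that("generate_phantom honors its construction guarantees", {
  ph <- generate_phantom(seed = 1, size = 128, n_trees = 1,
                         radius_range = c(2, 6), noise_sd = 0.05)
  expect_s3_class(ph, "ssfa_phantom")
  expect_identical(dim(ph$image), dim(ph$mask))
  expect_gte(max(ssfa:::.label_cpp(ph$mask + 0L, 8L)), 1L)
  expect_gte(min(ph$image), 0); expect_lte(max(ph$image), 1)
  # every planted branch contributes at least 20 foreground pixels
  for (b in ph$planted_graph) expect_gte(nrow(b$path), 20)
  # the mask covers every planted centerline vertex
  idx <- cbind(round(ph$planted_graph[[1]]$path[, 1]),
               round(ph$planted_graph[[1]]$path[, 2]))
  expect_true(all(ph$mask[idx]))
  expect_error(generate_phantom(seed = 1, size = 32), "size")
  expect_error(generate_phantom(seed = 1, size = 64, radius_range = c(0.5, 3)),
               "radius")
})

test_that("phantom generation is bit-identical under the same seed", {
  a <- generate_phantom(seed = 42, size = 96, n_trees = 2)
  b <- generate_phantom(seed = 42, size = 96, n_trees = 2)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$planted_graph, b$planted_graph)
  c <- generate_phantom(seed = 43, size = 96, n_trees = 2)
  expect_false(identical(a$image, c$image))
})

test_that("foreground fraction stays within the expected band", {
  fracs <- vapply(1:8, function(s) {
    ph <- generate_phantom(seed = s, size = 256, n_trees = 3,
                           radius_range = c(1, 10), noise_sd = 0.1)
    mean(ph$mask)
  }, numeric(1))
  expect_true(all(fracs > 0.01 & fracs < 0.40))
})

test_that("rasterized topology matches the planted branch structure", {
  ok <- 0L
  for (s in 1:20) {
    ph <- generate_phantom(seed = s, size = 128, n_trees = 1)
    g <- skeleton_to_graph(skeletonize(ph$mask))
    if (abs(n_edges(g) - ph$planted_edge_count) <= 2) ok <- ok + 1L
  }
  expect_gte(ok, 18L)   # >= 90% of seeds within +-2 edges
})

test_that("inject_fractures breaks exactly the requested edges", {
  # m = 0 is a no-op
  ph <- generate_phantom(seed = 5, size = 96, n_trees = 2)
  g <- skeleton_to_graph(skeletonize(ph$mask))
  inj0 <- inject_fractures(ph$mask, g, m = 0, gap_px = 15, seed = 1)
  expect_identical(inj0$mask, ph$mask)

  # four disjoint ribbons: breaking one splits exactly one component
  m <- multi_ribbon_mask(c(5, 5, 5, 5), w = 120)
  g <- skeleton_to_graph(skeletonize(m))
  expect_equal(n_edges(g), 4L)
  before <- max(ssfa:::.label_cpp(m + 0L, 8L))
  inj <- inject_fractures(m, g, m = 1, gap_px = 15, seed = 3)
  after <- max(ssfa:::.label_cpp(inj$mask + 0L, 8L))
  expect_equal(after, before + 1L)
  expect_length(inj$broken, 1L)
  # gap centerline is background; the chosen edge's midpoint is cleared
  path <- g$edges[[inj$broken]]$path
  mid <- path[(nrow(path) + 1) %/% 2, ]
  expect_false(inj$mask[mid[1], mid[2]])
  # no pixels added anywhere
  expect_true(all(inj$mask <= m))

  # breaking all eligible edges clears every midpoint
  inj_all <- inject_fractures(m, g, m = 4, gap_px = 15, seed = 3)
  for (e in g$edges) {
    mid <- e$path[(nrow(e$path) + 1) %/% 2, ]
    expect_false(inj_all$mask[mid[1], mid[2]])
  }
  expect_error(inject_fractures(m, g, m = 5, gap_px = 15, seed = 1),
               "insufficient eligible")
})

test_that("make_dataset writes the expected layout deterministically", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  man1 <- make_dataset(d1, 2, 3, 2, seed = 7, size = 64)
  expect_length(list.files(d1, pattern = "img_", recursive = TRUE), 7L)
  expect_length(list.files(d1, pattern = "mask_", recursive = TRUE), 4L)
  expect_setequal(vapply(man1$entries, `[[`, character(1), "role"),
                  c("labeled", "unlabeled", "test"))
  man2 <- make_dataset(d2, 2, 3, 2, seed = 7, size = 64)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  man3 <- make_dataset(file.path(tempdir(), "ds3"), 0, 0, 1, seed = 1,
                       size = 64)
  expect_length(man3$entries, 1L)
  unlink(c(d1, d2, file.path(tempdir(), "ds3")), recursive = TRUE)
})
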