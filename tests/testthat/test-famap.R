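test_that("ts_map is zero on empty input and constant on a uniform ribbon", {
  e <- matrix(FALSE, 16, 16)
  expect_equal(ts_map(e, 10), matrix(0, 16, 16))
  u <- ribbon_mask(32, 100, rows = 14:18, cols = 5:95)
  tu <- ts_map(u, 10)
  expect_length(unique(tu[u]), 1L)       # single occupied level
  expect_true(all(tu[!u] == 0))
})

test_that("ts_map scores thin branches above thick ones and stays in [0,1] quantized", {
  m <- multi_ribbon_mask(c(3, 11))
  ctr <- attr(m, "centers")
  ts <- ts_map(m, 10)
  expect_gte(min(ts), 0); expect_lte(max(ts), 1)
  # quantized to multiples of 1/L
  expect_true(all(abs(ts * 10 - round(ts * 10)) < 1e-9))
  thin <- mean(ts[(ctr[1] - 1):(ctr[1] + 1), 20:100])
  thick <- mean(ts[(ctr[2] - 5):(ctr[2] + 5), 20:100])
  expect_gt(thin, thick)
})

test_that("ts_map mean is non-increasing in branch width (widths 3,5,7,9,11)", {
  widths <- c(3, 5, 7, 9, 11)
  m <- multi_ribbon_mask(widths)
  ts <- ts_map(m, 10)
  ctr <- attr(m, "centers")
  means <- vapply(seq_along(widths), function(i) {
    half <- (widths[i] - 1) %/% 2
    mean(ts[(ctr[i] - half):(ctr[i] + half), 20:100])
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("ds_map is zero for identical inputs, symmetric, and covers deleted branches", {
  m <- multi_ribbon_mask(c(3, 9))
  expect_equal(ds_map(m, m), matrix(0, nrow(m), ncol(m)))
  ctr <- attr(m, "centers")
  m2 <- m
  m2[(ctr[1] - 1):(ctr[1] + 1), ] <- FALSE   # delete the thin branch
  d <- ds_map(m, m2)
  expect_gt(mean(d[(ctr[1] - 1):(ctr[1] + 1), 15:105] > 0), 0.95)
  expect_identical(ds_map(m, m2), ds_map(m2, m))
  expect_error(ds_map(m, matrix(FALSE, 2, 2)), "shape")
})

test_that("ds_map suppresses 1-px boundary jitter", {
  m <- multi_ribbon_mask(c(5, 9))
  dil <- ssfa:::as_logical_mat(ssfa:::.dilate_cpp(m + 0L, 1L))
  d <- ds_map(m, dil)
  expect_lt(mean(d > 0), 0.01)
})

test_that("compose_fa_map keeps channel order and round-trips", {
  ts1 <- matrix(0.3, 8, 8); ts2 <- matrix(0.7, 8, 8); ds <- matrix(1, 8, 8)
  fa <- compose_fa_map(ts1, ts2, ds)
  expect_equal(dim(fa), c(8, 8, 3))
  expect_equal(dimnames(fa)[[3]], c("ts1", "ts2", "ds"))
  expect_equal(fa[, , "ts1"], ts1)
  expect_equal(fa[, , "ts2"], ts2)
  expect_equal(fa[, , "ds"], ds)
  z <- compose_fa_map(ts1 * 0, ts2 * 0, ds * 0)
  expect_true(all(z == 0))
  expect_error(compose_fa_map(ts1, ts2, matrix(2, 8, 8)), "\\[0, 1\\]")
  expect_error(compose_fa_map(ts1, matrix(0, 4, 4), ds), "shape")
})

test_that("update_fa_map follows the convex blend exactly, non-recursively", {
  A0 <- array(0, dim = c(6, 6, 3))
  Ahat <- array(1, dim = c(6, 6, 3))
  st <- fa_state(A0, k = 0)
  expect_equal(update_fa_map(st, Ahat), A0)          # k = 0: frozen
  st <- fa_state(A0, k = 1)
  expect_equal(update_fa_map(st, Ahat), Ahat)        # k = 1: replace
  st <- fa_state(A0, k = 0.5)
  expect_equal(update_fa_map(st, Ahat), A0 + 0.5)
  # repeated updates always blend against A0, not the previous current map
  st <- fa_state(A0, k = 0.5)
  for (i in 1:5) last <- update_fa_map(st, Ahat)
  expect_equal(st$current, (1 - 0.5) * A0 + 0.5 * Ahat)
  A2 <- array(0.25, dim = c(6, 6, 3))
  update_fa_map(st, A2)
  expect_equal(st$current, 0.5 * A0 + 0.5 * A2)
  expect_error(fa_state(A0, k = 1.5), "k must lie")
})

test_that("init_fa_maps needs a trained predictor and duplicates the TS channel", {
  items <- phantom_items(2, 400)
  spec <- network_spec(depth = 2, base_channels = 4, fusion = "none")
  net <- build_network(spec, 1)
  expect_error(init_fa_maps(net, lapply(items, `[[`, "image")), "trained")
  net$trained <- TRUE
  maps <- init_fa_maps(net, lapply(items, `[[`, "image"), L = 10)
  expect_length(maps, 2)
  for (a in maps) {
    expect_equal(dim(a), c(64, 64, 3))
    expect_identical(a[, , 1], a[, , 2])
    expect_true(all(a[, , 3] == 0))
    expect_gte(min(a), 0); expect_lte(max(a), 1)
  }
  maps2 <- init_fa_maps(net, lapply(items, `[[`, "image"), L = 10)
  expect_identical(maps, maps2)
})
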