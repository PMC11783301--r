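test_that("skeletonize reduces a ribbon to a collinear 1-px line and is idempotent", {
  m <- ribbon_mask(20, 60, rows = 8:12, cols = 5:55)
  s <- skeletonize(m)
  px <- which(s, arr.ind = TRUE)
  expect_gt(nrow(px), 40)
  expect_length(unique(px[, 1]), 1L)          # collinear, width 1
  expect_true(all(s[m == FALSE] == FALSE))    # skeleton inside the mask
  expect_identical(skeletonize(s), s)         # idempotent
  # endpoints may retract, but by only a few pixels
  expect_lte(min(px[, 2]) - 5, 3)
  expect_lte(55 - max(px[, 2]), 3)
})

test_that("skeletonize handles empty and near-degenerate masks", {
  e <- matrix(FALSE, 10, 10)
  expect_identical(skeletonize(e), e)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_identical(skeletonize(one), one)
  # connectivity is preserved per component
  two <- matrix(FALSE, 30, 30)
  two[5:8, 5:25] <- TRUE
  two[20:23, 5:25] <- TRUE
  s <- skeletonize(two)
  expect_equal(max(ssfa:::.label_cpp(s + 0L, 8L)), 2L)
})

test_that("distance_map follows the 'adjacent-to-background is 1' convention", {
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  dm <- distance_map(one)
  expect_equal(dm$pixels[5, 5], 1)
  expect_true(all(dm$pixels[!one] == 0))

  # ribbon of width 7 (half-width 3): centerline distance within [3, 4]
  m <- ribbon_mask(30, 80, rows = 12:18, cols = 5:75)
  dm <- distance_map(m)
  expect_gte(dm$dmax, 3)
  expect_lte(dm$dmax, 4)
  # brute-force check on a few pixels
  bg <- which(!m, arr.ind = TRUE)
  for (p in list(c(15, 40), c(12, 40), c(13, 7))) {
    d_true <- sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
    expect_equal(dm$pixels[p[1], p[2]], d_true)
  }
  expect_error(distance_map(matrix(FALSE, 5, 5)), "empty")
})

test_that("threshold_ladder is the linear interpolation between dmin and dmax", {
  expect_equal(threshold_ladder(1, 11, 10), 2:11)
  expect_equal(threshold_ladder(2, 2, 7), rep(2, 7))   # degenerate
  tl <- threshold_ladder(1.5, 9.25, 10)
  expect_length(tl, 10)
  expect_true(all(diff(tl) > 0))
  expect_equal(tl[10], 9.25)
  expect_error(threshold_ladder(5, 4, 10), "dmax")
  expect_error(threshold_ladder(0, 4, 10), "dmin")
  expect_error(threshold_ladder(1, 4, 0), "L")
})
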