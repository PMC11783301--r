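test_that("fracture_rate is 0 for perfect and translated predictions, 100 for empty", {
  ph <- generate_phantom(seed = 11, size = 96, n_trees = 2)
  expect_equal(fracture_rate(ph$mask, ph$mask)$fr, 0)
  # translation by 3 px stays within delta = 5
  m <- ribbon_mask(40, 100, rows = 18:22, cols = 10:90)
  shifted <- matrix(FALSE, 40, 100)
  shifted[21:25, 13:93] <- TRUE
  expect_equal(fracture_rate(shifted, m, delta = 5)$fr, 0)
  empty <- matrix(FALSE, 96, 96)
  expect_equal(fracture_rate(empty, ph$mask)$fr, 100)
  expect_error(fracture_rate(ph$mask, empty), "no ground-truth topology")
})

test_that("fracture_rate matches the brute-force oracle and is monotone", {
  for (s in 1:4) {
    ph <- generate_phantom(seed = 700 + s, size = 64, n_trees = 1,
                           radius_range = c(1.5, 4))
    g <- skeleton_to_graph(skeletonize(ph$mask))
    m_max <- sum(vapply(g$edges, function(e) nrow(e$path), integer(1)) > 25)
    prev_fr <- -1
    for (m in 0:min(2, m_max)) {
      inj <- inject_fractures(ph$mask, g, m = m, gap_px = 15, seed = 5)
      rep <- fracture_rate(inj$mask, ph$mask, delta = 5)
      expect_identical(rep$per_edge,
                       oracle_fracture_verdicts(inj$mask, ph$mask, delta = 5))
      expect_gte(rep$fr, prev_fr)           # more breaks never lower FR
      prev_fr <- rep$fr
    }
  }
})

test_that("fracture_rate is non-increasing in delta", {
  ph <- generate_phantom(seed = 21, size = 96, n_trees = 2)
  g <- skeleton_to_graph(skeletonize(ph$mask))
  inj <- inject_fractures(ph$mask, g, m = 1, gap_px = 15, seed = 2)
  frs <- vapply(c(1, 3, 5, 8, 12),
                function(d) fracture_rate(inj$mask, ph$mask, delta = d)$fr,
                numeric(1))
  expect_true(all(diff(frs) <= 1e-12))
})

test_that("cl_dice matches closed-form cases", {
  m <- ribbon_mask(30, 110, rows = 13:17, cols = 5:105)
  expect_equal(cl_dice(m, m), 1)
  other <- matrix(FALSE, 30, 110); other[25:27, 5:105] <- TRUE
  expect_equal(cl_dice(m, other), 0)
  expect_equal(cl_dice(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), 1)
  expect_equal(cl_dice(m, matrix(FALSE, 30, 110)), 0)
  # half-ribbon: Tprec = 1, Tsens ~ 0.5 -> clDice ~ 2/3
  half <- m; half[, 56:110] <- FALSE
  cd <- cl_dice(half, m)
  expect_gt(cd, 2 / 3 - 0.06)
  expect_lt(cd, 2 / 3 + 0.06)
})

test_that("betti_errors counts components and holes with the (8, 4) duality", {
  a <- annulus_mask()
  expect_equal(unname(betti_errors(a, a)), c(0, 0, 0))
  two <- matrix(FALSE, 30, 30); two[5:8, 5:12] <- TRUE; two[20:24, 15:25] <- TRUE
  one <- matrix(FALSE, 30, 30); one[5:8, 5:25] <- TRUE
  expect_equal(unname(betti_errors(two, one)), c(1, 1, 0))
  broken <- a; broken[1:24, 23:25] <- FALSE   # cut the ring open
  be <- betti_errors(broken, a)
  expect_equal(unname(be), c(1, 0, 1))
  expect_equal(be[["beta"]], be[["beta0"]] + be[["beta1"]])
})

test_that("volumetric metrics match closed forms", {
  m <- ribbon_mask()
  expect_equal(unname(volumetric_metrics(m, m)), c(1, 1, 1))
  disj <- matrix(FALSE, 32, 100); disj[25:28, 5:95] <- TRUE
  vm <- volumetric_metrics(m, disj)
  expect_equal(vm[["dice"]], 0); expect_equal(vm[["jaccard"]], 0)
  # |P| = |Y| = 100, |P intersect Y| = 50
  P <- matrix(FALSE, 20, 20); Y <- matrix(FALSE, 20, 20)
  P[1:10, 1:10] <- TRUE
  Y[1:10, 6:15] <- TRUE
  vm <- volumetric_metrics(P, Y)
  expect_equal(vm[["dice"]], 0.5)
  expect_equal(vm[["jaccard"]], 1 / 3)
  e <- matrix(FALSE, 4, 4)
  expect_equal(unname(volumetric_metrics(e, e)), c(1, 1, 1))
})

test_that("Jaccard never exceeds Dice on random masks", {
  set.seed(99)
  for (i in 1:20) {
    P <- matrix(runif(400) < 0.4, 20, 20)
    Y <- matrix(runif(400) < 0.4, 20, 20)
    vm <- volumetric_metrics(P, Y)
    expect_lte(vm[["jaccard"]], vm[["dice"]] + 1e-12)
  }
})

test_that("metric_report bundles all metrics coherently", {
  ph <- generate_phantom(seed = 31, size = 96, n_trees = 2)
  r <- metric_report(ph$mask, ph$mask)
  expect_equal(r$fr, 0); expect_equal(r$cl_dice, 1); expect_equal(r$dice, 1)
  expect_equal(r$beta, r$beta0 + r$beta1)
})
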