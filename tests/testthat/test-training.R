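test_that("dice_loss matches its closed forms", {
  y <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  hard <- y + 0
  expect_lt(dice_loss(hard, y), 1e-5)
  expect_gt(dice_loss(matrix(0, 2, 2), y), 1 - 1e-4)
  # symmetric in mask-valued arguments
  a <- matrix(c(1, 0, 1, 0), 2, 2); b <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(a, as_mask(b)), dice_loss(b, as_mask(a)))
  expect_error(dice_loss(matrix(0, 2, 2), matrix(FALSE, 3, 3)), "shape")
})

test_that("lambda_schedule is the linear ramp", {
  expect_equal(lambda_schedule(0, 100, 0.2), 0)
  expect_equal(lambda_schedule(100, 100, 0.2), 0.2)
  expect_equal(lambda_schedule(50, 100, 0.2), 0.1)
  expect_error(lambda_schedule(1, 0, 0.2), "max_epoch")
  expect_error(lambda_schedule(-1, 10, 0.2), "epoch")
})

test_that("supervised pretraining reduces the loss and is deterministic", {
  items <- phantom_items(2, 500)
  cfg <- tiny_train_config(init_epochs = 5L)
  net <- pretrain_supervised(items, cfg)
  expect_true(net$trained)
  h <- net$history
  expect_lt(min(h[3:5]), h[1])              # best-so-far improves on epoch 1
  net2 <- pretrain_supervised(items, cfg)
  expect_identical(net$params, net2$params)
  maps <- init_fa_maps(net, lapply(items, `[[`, "image"))
  expect_length(maps, 2L)
  expect_error(pretrain_supervised(list(), cfg), "empty")
})

test_that("the step log satisfies the loss identity and the lambda ramp", {
  lab <- phantom_items(3, 520)
  unl <- phantom_items(4, 540)
  cfg <- tiny_train_config()
  st <- ssfa_train(lab, unl, cfg)
  expect_gt(length(st$steps), 0)
  for (s in st$steps) {
    expect_equal(s$l_total, s$l_sup + s$lambda * s$l_unsup, tolerance = 1e-9)
    expect_equal(s$lambda,
                 lambda_schedule(s$epoch, cfg$max_epoch, cfg$lambda_max))
  }
})

test_that("k = 0 freezes every attention map at its initial value", {
  lab <- phantom_items(3, 560)
  cfg <- tiny_train_config(k = 0)
  st <- ssfa_train(lab, list(), cfg)
  for (fs in st$fa_states) expect_identical(fs$current, fs$A0)
})

test_that("lambda_max = 0 silences the unsupervised term", {
  lab <- phantom_items(3, 580)
  unl <- phantom_items(3, 590)
  cfg <- tiny_train_config(lambda_max = 0)
  st <- ssfa_train(lab, unl, cfg)
  for (s in st$steps) {
    expect_identical(s$l_total, s$l_sup)
  }
})

test_that("after one epoch the maps equal the blend of A0 and the regenerated map", {
  lab <- phantom_items(3, 600)
  cfg <- tiny_train_config(max_epoch = 1L, k = 0.6)
  st <- ssfa_train(lab, list(), cfg)
  for (fs in st$fa_states) {
    expect_false(is.null(fs$current))
    expect_gte(min(fs$current), 0); expect_lte(max(fs$current), 1)
  }
  # recompute A_hat^1 from the returned predictors and the initial maps
  items_in_state_order <- c(lab[setdiff(seq_along(lab), st$val_idx)],
                            lab[st$val_idx])
  for (i in seq_along(items_in_state_order)) {
    img <- items_in_state_order[[i]]$image
    fs <- st$fa_states[[i]]
    P1 <- ssfa:::net_forward(st$predictor1, img, fs$A0)$prob >= 0.5
    P2 <- ssfa:::net_forward(st$predictor2, img, fs$A0)$prob >= 0.5
    A_hat <- ssfa:::fa_map_from_predictions(P1, P2, cfg$L, cfg$rho)
    expect_equal(fs$current, (1 - cfg$k) * fs$A0 + cfg$k * A_hat,
                 tolerance = 1e-12)
  }
})

test_that("two-stage inference returns a well-formed deterministic mask", {
  lab <- phantom_items(4, 620)
  cfg <- tiny_train_config()
  st <- ssfa_train(lab, list(), cfg)
  img <- phantom_items(1, 640)[[1]]$image
  m1 <- two_stage_inference(st, img)
  m2 <- two_stage_inference(st, img)
  expect_identical(m1, m2)
  expect_true(is.logical(m1))
  expect_identical(dim(m1), dim(img))
  expect_warning(
    two_stage_inference(structure(unclass(st)[setdiff(names(st), "init_predictor")],
                                  class = "ssfa_dual_state"), img),
    "zero FA map")
})
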