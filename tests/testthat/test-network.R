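test_that("builds are deterministic per seed and differ across seeds", {
  spec <- network_spec(depth = 3, base_channels = 4, fusion = "multiple")
  a <- build_network(spec, 7); b <- build_network(spec, 7)
  expect_identical(a$params, b$params)
  c <- build_network(spec, 8)
  expect_false(identical(a$params, c$params))
  img <- matrix(runif(32 * 32), 32, 32)
  fa <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_prob(a, img, fa), predict_prob(b, img, fa))
  expect_false(identical(predict_prob(a, img, fa), predict_prob(c, img, fa)))
})

test_that("fusion variants differ in parameter count as expected", {
  n_ch <- param_count(build_network(network_spec(3, 8, "channel"), 5))
  n_si <- param_count(build_network(network_spec(3, 8, "single"), 5))
  n_mu <- param_count(build_network(network_spec(3, 8, "multiple"), 5))
  expect_lt(n_ch, n_mu)
  expect_lt(n_si, n_mu)
  expect_error(network_spec(3, 8, "banana"))
})

test_that("forward pass keeps the shape contract and valid probabilities", {
  for (fusion in c("none", "channel", "single", "multiple")) {
    net <- build_network(network_spec(3, 4, fusion), 3)
    img <- matrix(runif(48 * 64), 48, 64)
    fa <- array(runif(48 * 64 * 3), c(48, 64, 3))
    p <- predict_prob(net, img, fa)
    expect_identical(dim(p), dim(img))
    expect_gte(min(p), 0); expect_lte(max(p), 1)
  }
  # zero FA map must not annihilate the signal
  net <- build_network(network_spec(3, 4, "multiple"), 3)
  img <- matrix(runif(32 * 32), 32, 32)
  p0 <- predict_prob(net, img, NULL)
  expect_true(all(is.finite(p0)))
  expect_gt(stats::sd(p0), 0)
  # doubling base_channels changes values, not shape
  net2 <- build_network(network_spec(3, 8, "multiple"), 3)
  p2 <- predict_prob(net2, img, NULL)
  expect_identical(dim(p2), dim(p0))
  expect_false(identical(p2, p0))
  # non-divisible dims are refused with advice
  expect_error(predict_prob(net, matrix(0.5, 33, 32)), "divisible")
  expect_error(predict_prob(net, img, array(0, c(16, 16, 3))), "aligned")
})

test_that("hand-written backprop matches finite differences", {
  set.seed(5)
  for (fusion in c("channel", "multiple")) {
    spec <- network_spec(depth = 2, base_channels = 2, fusion = fusion)
    net <- build_network(spec, 11)
    img <- matrix(runif(64), 8, 8)
    fa <- array(runif(192), c(8, 8, 3))
    y <- matrix(runif(64) > 0.6, 8, 8)
    fwd <- ssfa:::net_forward(net, img, fa, keep_tape = TRUE)
    g <- ssfa:::net_backward(net, fwd, ssfa:::dice_loss_grad(fwd$prob, y))
    lossf <- function() dice_loss(ssfa:::net_forward(net, img, fa)$prob, y)
    eps <- 1e-6
    paths <- list(list("img", 1L, "W1"), list("dec", 1L, "g2"),
                  list("head", NULL, "W"))
    if (fusion == "multiple") paths <- c(paths, list(list("fa", 1L, "W2")))
    for (pp in paths) {
      get_w <- function() if (is.null(pp[[2]])) net$params[[pp[[1]]]][[pp[[3]]]]
                          else net$params[[pp[[1]]]][[pp[[2]]]][[pp[[3]]]]
      set_w <- function(w) {
        if (is.null(pp[[2]])) net$params[[pp[[1]]]][[pp[[3]]]] <- w
        else net$params[[pp[[1]]]][[pp[[2]]]][[pp[[3]]]] <- w
      }
      gv <- if (is.null(pp[[2]])) g[[pp[[1]]]][[pp[[3]]]]
            else g[[pp[[1]]]][[pp[[2]]]][[pp[[3]]]]
      w <- get_w()
      for (j in sample(length(w), min(3, length(w)))) {
        w0 <- w[j]
        w[j] <- w0 + eps; set_w(w); lp <- lossf()
        w[j] <- w0 - eps; set_w(w); lm <- lossf()
        w[j] <- w0; set_w(w)
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - gv[j]) / max(1e-8, abs(num) + abs(gv[j])), 1e-4)
      }
    }
  }
})

test_that("gradients reach both encoders under multiplicative fusion", {
  net <- build_network(network_spec(3, 4, "multiple"), 9)
  img <- matrix(runif(32 * 32), 32, 32)
  fa <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(runif(32 * 32) > 0.5, 32, 32)
  fwd <- ssfa:::net_forward(net, img, fa, keep_tape = TRUE)
  g <- ssfa:::net_backward(net, fwd, ssfa:::dice_loss_grad(fwd$prob, y))
  for (i in seq_along(g$img)) {
    expect_gt(sum(abs(g$img[[i]]$W1)), 0, label = sprintf("img level %d", i))
  }
  for (i in seq_along(g$fa)) {
    expect_gt(sum(abs(g$fa[[i]]$W1)), 0, label = sprintf("fa level %d", i))
  }
})
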