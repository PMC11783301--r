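# Dual-encoder encoder-decoder segmentation network.
#
# The Raw Image Encoder and the FA (attention) Encoder run in parallel;
# before each downsampling the image features are multiplied element-wise
# by the FA branch's attention output, and the *product* feeds both the
# skip connection and the next image-encoder level, while the FA branch's
# next level consumes its own (un-fused) output. The FA branch's level
# output passes through 1 + tanh(.), range (0, 2), so an all-zero
# attention map multiplies by ~1 instead of annihilating the signal.
# Three fusion variants are supported: "multiple" (fusion at every level),
# "single" (first level only), "channel" (no FA encoder; the 3 attention
# channels are concatenated to the image as a 4-channel input). "none" is
# a plain image-only UNet, used for supervised pretraining.
#
# There is no autodiff framework in the supported dependency set, so the
# reverse pass is written by hand and verified against finite differences
# in the test suite.

NORM_EPS <- 1e-5

#' Describe a segmentation network
#'
#' @param depth Number of resolution levels (>= 2; default 5).
#' @param base_channels Channels at the first level, doubled per level
#'   (default 64; use 8 for desk-scale runs).
#' @param fusion One of `"multiple"`, `"single"`, `"channel"`, `"none"`.
#' @param norm `"group"` (per-channel normalization, batch-size
#'   independent) or `"none"`.
#' @return A `ssfa_network_spec` list.
#' @export
network_spec <- function(depth = 5L, base_channels = 64L,
                         fusion = c("multiple", "single", "channel", "none"),
                         norm = c("group", "none")) {
  fusion <- match.arg(fusion)
  norm <- match.arg(norm)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 fusion = fusion, norm = norm,
                 in_channels_image = 1L, in_channels_fa = 3L,
                 out_classes = 2L),
            class = "ssfa_network_spec")
}

#' Build a randomly initialized predictor
#'
#' He-normal initialization for convolution weights; normalization gains
#' start at 1, biases at 0. Two builds with the same seed are identical;
#' different seeds give different parameters (the mechanism behind the
#' dual-branch disagreement).
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `ssfa_predictor`.
#' @export
build_network <- function(spec, seed) {
  stopifnot(inherits(spec, "ssfa_network_spec"))
  ch <- spec$base_channels * 2L^(seq_len(spec$depth) - 1L)
  in_img <- if (spec$fusion == "channel") 4L else 1L
  local_seed(seed, {
    params <- list()
    params$img <- vector("list", spec$depth)
    prev <- in_img
    for (i in seq_len(spec$depth)) {
      params$img[[i]] <- init_block(prev, ch[i], spec$norm)
      prev <- ch[i]
    }
    n_fa <- switch(spec$fusion, multiple = spec$depth - 1L, single = 1L, 0L)
    if (n_fa > 0) {
      params$fa <- vector("list", n_fa)
      prev <- spec$in_channels_fa
      for (i in seq_len(n_fa)) {
        params$fa[[i]] <- init_block(prev, ch[i], spec$norm)
        prev <- ch[i]
      }
    }
    params$dec <- vector("list", spec$depth - 1L)
    for (i in seq_len(spec$depth - 1L)) {
      params$dec[[i]] <- init_block(ch[i] + ch[i + 1L], ch[i], spec$norm)
    }
    params$head <- list(W = init_w(1L, ch[1], spec$out_classes),
                        b = numeric(spec$out_classes))
    pred <- new.env(parent = emptyenv())
    pred$spec <- spec
    pred$params <- params
    pred$init_seed <- as.integer(seed)
    pred$trained <- FALSE
    class(pred) <- "ssfa_predictor"
    pred
  })
}

init_w <- function(k, cin, cout) {
  fan_in <- k * k * cin
  matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
}

init_block <- function(cin, cout, norm) {
  b <- list(W1 = init_w(3L, cin, cout), b1 = numeric(cout),
            W2 = init_w(3L, cout, cout), b2 = numeric(cout))
  if (norm == "group") {
    b$g1 <- rep(1, cout); b$be1 <- numeric(cout)
    b$g2 <- rep(1, cout); b$be2 <- numeric(cout)
  }
  b
}

#' Number of trainable parameters
#' @param pred An `ssfa_predictor`.
#' @return Integer parameter count.
#' @export
param_count <- function(pred) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(pred$params)
  n
}

## ---- primitive fw/bw -------------------------------------------------

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# bilinear x2 interpolation as a pair of small matrix products:
# Y = Rw %*% X %*% t(Cw). The interpolation matrices are memoized per size.
.up_cache <- new.env(parent = emptyenv())

up_matrix <- function(n) {
  key <- as.character(n)
  m <- .up_cache[[key]]
  if (!is.null(m)) return(m)
  M <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    s <- (i - 0.5) / 2 + 0.5  # source position, 1-based
    i0 <- floor(s)
    w <- s - i0
    if (i0 < 1) { i0 <- 1L; i1 <- 1L; w <- 0 }
    else if (i0 >= n) { i0 <- n; i1 <- n; w <- 0 }
    else i1 <- i0 + 1L
    M[i, i0] <- M[i, i0] + (1 - w)
    M[i, i1] <- M[i, i1] + w
  }
  .up_cache[[key]] <- M
  M
}

up2_fw <- function(x) {
  d <- dim(x)
  Rw <- up_matrix(d[1]); Cw <- up_matrix(d[2])
  out <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  for (ci in seq_len(d[3])) out[, , ci] <- Rw %*% x[, , ci] %*% t(Cw)
  out
}

up2_bw <- function(gy, H, W) {
  d <- dim(gy)
  Rw <- up_matrix(H); Cw <- up_matrix(W)
  dx <- array(0, dim = c(H, W, d[3]))
  for (ci in seq_len(d[3])) dx[, , ci] <- t(Rw) %*% gy[, , ci] %*% Cw
  dx
}

# conv(3x3)-norm-relu, conv(3x3)-norm, then either relu (standard block)
# or 1 + tanh (FA attention block). The forward pass caches the im2col
# matrices and normalization statistics for the reverse pass; with
# `keep = FALSE` (inference) no caches are built or returned.
block_fw <- function(p, x, norm, final = c("relu", "attn"), keep = TRUE) {
  final <- match.arg(final)
  if (!keep) {
    a1 <- .conv2d_fwonly_cpp(x, p$W1, p$b1, 3L)
    if (norm == "group") a1 <- .inorm_fw_cpp(a1, p$g1, p$be1, NORM_EPS)$y
    r1 <- pmax(a1, 0)
    a2 <- .conv2d_fwonly_cpp(r1, p$W2, p$b2, 3L)
    if (norm == "group") a2 <- .inorm_fw_cpp(a2, p$g2, p$be2, NORM_EPS)$y
    out <- if (final == "relu") pmax(a2, 0) else 1 + tanh(a2)
    return(list(out = out, final = final))
  }
  cache <- list(cin = dim(x)[3])
  cv <- .conv2d_fw_cpp(x, p$W1, p$b1, 3L)
  cache$col1 <- cv$col
  if (norm == "group") {
    n1 <- .inorm_fw_cpp(cv$y, p$g1, p$be1, NORM_EPS)
    cache$n1 <- n1
    a1 <- n1$y
  } else a1 <- cv$y
  r1 <- pmax(a1, 0)
  cache$r1 <- r1
  cache$c1pos <- a1 > 0
  cv <- .conv2d_fw_cpp(r1, p$W2, p$b2, 3L)
  cache$col2 <- cv$col
  if (norm == "group") {
    n2 <- .inorm_fw_cpp(cv$y, p$g2, p$be2, NORM_EPS)
    cache$n2 <- n2
    a2 <- n2$y
  } else a2 <- cv$y
  if (final == "relu") {
    out <- pmax(a2, 0)
    cache$c2pos <- a2 > 0
  } else {
    th <- tanh(a2)
    out <- 1 + th
    cache$th <- th
  }
  cache$out <- out
  cache$final <- final
  cache
}

block_bw <- function(p, cache, norm, gout) {
  if (cache$final == "relu") {
    da2 <- gout * cache$c2pos
  } else {
    da2 <- gout * (1 - cache$th^2)
  }
  g <- list()
  if (norm == "group") {
    nb <- .inorm_bw_cpp(cache$n2$xhat, cache$n2$istd, p$g2, da2)
    g$g2 <- as.numeric(nb$dgamma); g$be2 <- as.numeric(nb$dbeta)
    dc2 <- nb$dx
  } else dc2 <- da2
  cb <- .conv2d_bw_cpp(cache$col2, p$W2, dc2, 3L, dim(cache$r1)[3])
  g$W2 <- cb$dW; g$b2 <- as.numeric(cb$db)
  da1 <- cb$dx * cache$c1pos
  if (norm == "group") {
    nb <- .inorm_bw_cpp(cache$n1$xhat, cache$n1$istd, p$g1, da1)
    g$g1 <- as.numeric(nb$dgamma); g$be1 <- as.numeric(nb$dbeta)
    dc1 <- nb$dx
  } else dc1 <- da1
  cb <- .conv2d_bw_cpp(cache$col1, p$W1, dc1, 3L, cache$cin)
  g$W1 <- cb$dW; g$b1 <- as.numeric(cb$db)
  g$dx <- cb$dx
  g
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

## ---- full network fw/bw ----------------------------------------------

check_input_dims <- function(spec, hw) {
  div <- 2L^(spec$depth - 1L)
  if (hw[1] %% div != 0 || hw[2] %% div != 0) {
    stop(sprintf(
      "input dims %dx%d not divisible by 2^(depth-1) = %d: pad or resize first",
      hw[1], hw[2], div), call. = FALSE)
  }
}

net_forward <- function(pred, image, fa = NULL, keep_tape = FALSE) {
  spec <- pred$spec
  hw <- dim(image)
  check_input_dims(spec, hw)
  if (is.null(fa)) fa <- zero_fa_map(hw[1], hw[2])
  if (!identical(dim(fa)[1:2], hw)) {
    stop("image and FA map are not spatially aligned", call. = FALSE)
  }
  p <- pred$params
  norm <- spec$norm
  depth <- spec$depth
  x <- if (spec$fusion == "channel") concat_c(as_cube(image), fa)
       else as_cube(image)
  f <- fa
  tape <- list(img = vector("list", depth), fa = list(), dec = list(),
               pool_img = vector("list", depth - 1L), pool_fa = list(),
               fused_in = vector("list", depth))
  n_fa <- length(p$fa %||% list())
  skips <- vector("list", depth - 1L)
  for (i in seq_len(depth - 1L)) {
    bi <- block_fw(p$img[[i]], x, norm, "relu", keep_tape)
    tape$img[[i]] <- bi
    ximg <- bi$out
    if (i <= n_fa) {
      bf <- block_fw(p$fa[[i]], f, norm, "attn", keep_tape)
      tape$fa[[i]] <- bf
      fused <- ximg * bf$out
      if (i < n_fa) {
        pf <- .maxpool2_fw_cpp(bf$out)
        tape$pool_fa[[i]] <- list(arg = pf$argmax, hw = dim(bf$out)[1:2])
        f <- pf$y
      }
    } else {
      fused <- ximg
    }
    skips[[i]] <- fused
    px <- .maxpool2_fw_cpp(fused)
    tape$pool_img[[i]] <- list(arg = px$argmax, hw = dim(fused)[1:2])
    x <- px$y
  }
  bb <- block_fw(p$img[[depth]], x, norm, "relu", keep_tape)
  tape$img[[depth]] <- bb
  x <- bb$out
  for (i in rev(seq_len(depth - 1L))) {
    up <- up2_fw(x)
    cat_in <- concat_c(up, skips[[i]])
    bd <- block_fw(p$dec[[i]], cat_in, norm, "relu", keep_tape)
    tape$dec[[i]] <- c(bd, list(up_hw = dim(x)[1:2], n_up = dim(up)[3]))
    x <- bd$out
  }
  if (keep_tape) {
    hd <- .conv2d_fw_cpp(x, p$head$W, p$head$b, 1L)
    logits <- hd$y
  } else {
    logits <- .conv2d_fwonly_cpp(x, p$head$W, p$head$b, 1L)
  }
  z1 <- logits[, , 1L]; z2 <- logits[, , 2L]
  mx <- pmax(z1, z2)
  e1 <- exp(z1 - mx); e2 <- exp(z2 - mx)
  prob <- e1 / (e1 + e2)
  out <- list(prob = prob)
  if (keep_tape) {
    tape$head_col <- hd$col
    tape$head_cin <- dim(x)[3]
    tape$skips_n <- depth - 1L
    out$tape <- tape
  }
  out
}

# gprob: dLoss/dprob (foreground probability). Returns gradients in the
# same nested shape as pred$params.
net_backward <- function(pred, fwd, gprob) {
  spec <- pred$spec
  p <- pred$params
  tape <- fwd$tape
  norm <- spec$norm
  depth <- spec$depth
  prob <- fwd$prob
  grads <- list()
  # softmax (2 classes): dz1 = g * p(1-p), dz2 = -dz1
  dz1 <- gprob * prob * (1 - prob)
  dlogits <- array(0, dim = c(dim(prob), 2L))
  dlogits[, , 1L] <- dz1
  dlogits[, , 2L] <- -dz1
  hb <- .conv2d_bw_cpp(tape$head_col, p$head$W, dlogits, 1L, tape$head_cin)
  grads$head <- list(W = hb$dW, b = as.numeric(hb$db))
  dx <- hb$dx
  # decoder
  grads$dec <- vector("list", depth - 1L)
  dskips <- vector("list", depth - 1L)
  for (i in seq_len(depth - 1L)) {
    td <- tape$dec[[i]]
    gb <- block_bw(p$dec[[i]], td, norm, dx)
    grads$dec[[i]] <- gb[setdiff(names(gb), "dx")]
    dcat <- gb$dx
    n_up <- td$n_up
    dup <- dcat[, , seq_len(n_up), drop = FALSE]
    dskips[[i]] <- dcat[, , n_up + seq_len(dim(dcat)[3] - n_up), drop = FALSE]
    dx <- up2_bw(dup, td$up_hw[1], td$up_hw[2])
  }
  # bottom block
  gb <- block_bw(p$img[[depth]], tape$img[[depth]], norm, dx)
  grads$img <- vector("list", depth)
  grads$img[[depth]] <- gb[setdiff(names(gb), "dx")]
  dpooled <- gb$dx
  n_fa <- length(p$fa %||% list())
  if (n_fa > 0) grads$fa <- vector("list", n_fa)
  dfa_chain <- NULL  # gradient w.r.t. pooled FA features entering level i+1
  for (i in rev(seq_len(depth - 1L))) {
    pl <- tape$pool_img[[i]]
    dfused <- .maxpool2_bw_cpp(dpooled, pl$arg, pl$hw[1], pl$hw[2]) +
      dskips[[i]]
    bi <- tape$img[[i]]
    if (i <= n_fa) {
      bf <- tape$fa[[i]]
      dximg <- dfused * bf$out
      dfatt <- dfused * bi$out
      if (i < n_fa) {
        pf <- tape$pool_fa[[i]]
        dfatt <- dfatt + .maxpool2_bw_cpp(dfa_chain, pf$arg, pf$hw[1], pf$hw[2])
      }
      gf <- block_bw(p$fa[[i]], bf, norm, dfatt)
      grads$fa[[i]] <- gf[setdiff(names(gf), "dx")]
      dfa_chain <- gf$dx
    } else {
      dximg <- dfused
    }
    gb <- block_bw(p$img[[i]], bi, norm, dximg)
    grads$img[[i]] <- gb[setdiff(names(gb), "dx")]
    dpooled <- gb$dx
  }
  grads
}

## ---- prediction API --------------------------------------------------

#' Per-pixel foreground probability
#'
#' @param pred An `ssfa_predictor`.
#' @param image Grayscale matrix in `[0, 1]` with dims divisible by
#'   `2^(depth - 1)`.
#' @param fa Optional 3-channel FA map; a zero map is used when missing
#'   (and for `fusion = "none"` networks the map is ignored).
#' @return Numeric matrix of foreground probabilities in `[0, 1]`.
#' @export
predict_prob <- function(pred, image, fa = NULL) {
  stopifnot(inherits(pred, "ssfa_predictor"))
  if (pred$spec$fusion == "none") fa <- NULL
  net_forward(pred, image, fa)$prob
}

#' Binarized prediction (probability >= 0.5)
#' @inheritParams predict_prob
#' @param threshold Binarization threshold (default 0.5).
#' @return Logical mask.
#' @export
predict_mask <- function(pred, image, fa = NULL, threshold = 0.5) {
  predict_prob(pred, image, fa) >= threshold
}

#' @export
print.ssfa_predictor <- function(x, ...) {
  cat(sprintf(
    "<predictor: depth %d, base %d, fusion '%s', %s params, seed %d%s>\n",
    x$spec$depth, x$spec$base_channels, x$spec$fusion,
    format(param_count(x), big.mark = ","), x$init_seed,
    if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

## ---- optimizer -------------------------------------------------------

# Map two same-shaped nested lists of numeric leaves. Lists are matched by
# name where names exist (gradient lists are not built in the same order
# as parameter lists), by position otherwise.
map_leaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (nm in keys) {
      if (!is.null(a[[nm]])) out[[nm]] <- map_leaves(a[[nm]], b[[nm]], f)
    }
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

scale_grads <- function(g, s) {
  if (is.list(g)) lapply(g, scale_grads, s = s) else g * s
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  map_leaves(a, b, `+`)
}

sgd_state <- function(params) list(v = zero_like(params))

# SGD with momentum and decoupled-from-nothing classic weight decay
# (decay added to the gradient), as is conventional for this family of
# segmentation models.
sgd_step <- function(pred, grads, state, lr, momentum = 0.9,
                     weight_decay = 5e-5) {
  state$v <- map_leaves(state$v, map_leaves(grads, pred$params,
                                            function(g, w) g + weight_decay * w),
                        function(v, g) momentum * v + g)
  pred$params <- map_leaves(pred$params, state$v, function(w, v) w - lr * v)
  state
}
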