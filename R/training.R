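# Semi-supervised dual-network training with cross pseudo supervision and
# the per-epoch attention-map update, plus supervised pretraining for
# initialization and the two-stage inference procedure.

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)` on the foreground
#' probability, `eps = 1e-5`.
#'
#' @param prob Foreground probability matrix in `[0, 1]`.
#' @param target Logical target mask of the same shape.
#' @return Loss value in `[0, 1]`.
#' @export
dice_loss <- function(prob, target, eps = 1e-5) {
  check_same_shape(prob, target, "probability and target")
  y <- target + 0
  1 - (2 * sum(prob * y) + eps) / (sum(prob) + sum(y) + eps)
}

# dLoss/dprob for the soft Dice loss above
dice_loss_grad <- function(prob, target, eps = 1e-5) {
  y <- target + 0
  num <- 2 * sum(prob * y) + eps
  den <- sum(prob) + sum(y) + eps
  -(2 * y * den - num) / den^2
}

#' Consistency-weight schedule
#'
#' The unsupervised loss weight grows linearly over training:
#' `lambda = lambda_max * epoch / max_epoch`.
#'
#' @param epoch Current epoch, `0 <= epoch <= max_epoch`.
#' @param max_epoch Total number of epochs (> 0).
#' @param lambda_max Final weight.
#' @return The weight at `epoch`.
#' @export
lambda_schedule <- function(epoch, max_epoch, lambda_max) {
  if (max_epoch <= 0) stop("max_epoch must be > 0", call. = FALSE)
  if (epoch < 0 || epoch > max_epoch) {
    stop("epoch must lie in [0, max_epoch]", call. = FALSE)
  }
  lambda_max * epoch / max_epoch
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: SGD with momentum 0.9,
#' weight decay 5e-5, batch 16, 100 epochs, initial learning rate 0.1
#' halved every 25 epochs, flip/rotation/transposition augmentation,
#' 256x256 inputs, attention levels `L = 10`, matching tolerance
#' `delta = 5`. `lambda_max = 3` and `k = 0.6` follow the choice for the
#' smallest reference dataset, the regime closest to desk-scale synthetic
#' data. Every field can be overridden.
#'
#' @param ... Named overrides of the defaults listed above, plus network
#'   fields `depth`, `base_channels`, `fusion`, `norm`, pretraining length
#'   `init_epochs`, validation fraction `val_frac` and `seeds` (named
#'   vector `net1`, `net2`, `data`).
#' @return An `ssfa_train_config` list.
#' @export
train_config <- function(...) {
  cfg <- list(
    lambda_max = 3, k = 0.6, L = 10L, delta = 5, rho = 2,
    max_epoch = 100L, batch = 16L,
    lr = 0.1, momentum = 0.9, weight_decay = 5e-5,
    lr_decay = c(factor = 0.5, every = 25),
    augmentations = c("flip", "rotation", "transposition"),
    image_size = 256L,
    depth = 5L, base_channels = 64L, fusion = "multiple", norm = "group",
    init_epochs = 10L, val_frac = 0.2,
    seeds = c(net1 = 1L, net2 = 2L, data = 3L)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$k < 0 || cfg$k > 1) stop("k must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "ssfa_train_config")
}

#' Desk-scale training profile
#'
#' A configuration small enough for a single CPU: 64x64 inputs, depth 3,
#' 8 base channels, batch 4, 20 epochs, per-channel (group-style)
#' normalization. Intended for the synthetic phantom datasets.
#'
#' @param ... Further overrides, as in [train_config()].
#' @return An `ssfa_train_config`.
#' @export
desk_config <- function(...) {
  train_config(image_size = 64L, depth = 3L, base_channels = 8L,
               batch = 4L, max_epoch = 20L, init_epochs = 10L,
               norm = "group", ...)
}

current_lr <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay[["factor"]]^floor((epoch - 1) / cfg$lr_decay[["every"]])
}

# One of the 8 dihedral symmetries, drawn from the configured augmentation
# set; applied identically to image, mask and FA channels so attention
# stays registered to the image.
sample_aug <- function(cfg) {
  ops <- character(0)
  if ("flip" %in% cfg$augmentations) ops <- c(ops, "fliph", "flipv")
  if ("rotation" %in% cfg$augmentations) ops <- c(ops, "rot90", "rot180", "rot270")
  if ("transposition" %in% cfg$augmentations) ops <- c(ops, "transpose")
  ops <- c("identity", ops)
  sample(ops, 1)
}

apply_aug <- function(x, op) {
  if (length(dim(x)) == 3L) {
    out <- lapply(seq_len(dim(x)[3]), function(i) apply_aug(x[, , i], op))
    return(array(unlist(out), dim = c(dim(out[[1]]), length(out))))
  }
  switch(op,
         identity = x,
         fliph = x[, rev(seq_len(ncol(x))), drop = FALSE],
         flipv = x[rev(seq_len(nrow(x))), , drop = FALSE],
         rot90 = t(x)[rev(seq_len(ncol(x))), , drop = FALSE],
         rot180 = x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE],
         rot270 = t(x)[, rev(seq_len(nrow(x))), drop = FALSE],
         transpose = t(x))
}

check_items <- function(items, need_mask = TRUE, what = "data") {
  for (it in items) {
    stopifnot(is.matrix(it$image))
    if (need_mask && is.null(it$mask)) {
      stop(sprintf("%s items must carry masks", what), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Supervised pretraining of a single-branch UNet
#'
#' Trains a plain image-only (fusion-free) UNet with the Dice loss on the
#' labeled images. Used to produce the initial FA maps and as the
#' fully-supervised baseline.
#'
#' @param labeled List of items, each a list with `image` (matrix in
#'   `[0, 1]`) and `mask` (logical).
#' @param config An [train_config()]; `init_epochs` epochs are run unless
#'   `epochs` overrides.
#' @param seed Initialization seed (default `config$seeds["net1"]`).
#' @param epochs Number of epochs; defaults to `config$init_epochs`.
#' @return A trained `ssfa_predictor` with a `history` field (mean epoch
#'   loss).
#' @export
pretrain_supervised <- function(labeled, config = desk_config(),
                                seed = NULL, epochs = NULL) {
  if (!length(labeled)) stop("labeled set is empty", call. = FALSE)
  check_items(labeled, TRUE, "labeled")
  seed <- seed %||% config$seeds[["net1"]]
  epochs <- epochs %||% config$init_epochs
  spec <- network_spec(depth = config$depth,
                       base_channels = config$base_channels,
                       fusion = "none", norm = config$norm)
  net <- build_network(spec, seed)
  st <- sgd_state(net$params)
  history <- numeric(epochs)
  data_seed <- derive_seed(config$seeds[["data"]], 101L)
  local_seed(data_seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(labeled))
      lr <- current_lr(config, ep)
      losses <- numeric(0)
      for (batch in split(ord, ceiling(seq_along(ord) / config$batch))) {
        acc <- NULL
        bl <- 0
        for (i in batch) {
          op <- sample_aug(config)
          img <- apply_aug(labeled[[i]]$image, op)
          y <- apply_aug(labeled[[i]]$mask, op)
          fwd <- net_forward(net, img, NULL, keep_tape = TRUE)
          l <- dice_loss(fwd$prob, y)
          if (!is.finite(l)) stop("NaN loss in supervised pretraining",
                                  call. = FALSE)
          bl <- bl + l
          g <- net_backward(net, fwd, dice_loss_grad(fwd$prob, y))
          acc <- add_grads(acc, g)
        }
        losses <- c(losses, bl / length(batch))
        st <- sgd_step(net, scale_grads(acc, 1 / length(batch)), st, lr,
                       config$momentum, config$weight_decay)
      }
      history[ep] <- mean(losses)
    }
  })
  net$trained <- TRUE
  net$history <- history
  net
}

#' Semi-supervised dual-network training
#'
#' Two identically shaped networks with different initializations are
#' trained jointly. On labeled images each network minimises the Dice
#' loss against the ground truth (`L_sup`); on unlabeled images each
#' network is supervised by the *other* network's hard (argmax,
#' gradient-detached) pseudo-label (`L_unsup`), weighted by the linear
#' schedule [lambda_schedule()]; the step objective is
#' `L_total = L_sup + lambda * L_unsup`. Every image carries an attention
#' map: initialised from a supervised pretrained UNet, and after each
#' epoch regenerated from the two binarized predictions and blended as
#' `(1 - k) * A0 + k * A_hat`. A fraction of the labeled images is held
#' out; the branch with the higher held-out Dice at the best epoch is the
#' branch used at inference.
#'
#' @param labeled List of items with `image` and `mask`.
#' @param unlabeled List of items with `image` (may be empty, degrading to
#'   dual supervised training).
#' @param config An [train_config()] / [desk_config()].
#' @param init_predictor Optional pretrained single-branch predictor; when
#'   missing one is pretrained on the labeled training split.
#' @return An `ssfa_dual_state`: list with `predictor1`, `predictor2`,
#'   `init_predictor`, `fa_states`, `best_branch`, `best_val_dice`,
#'   `history` (per-epoch data frame), `steps` (per-step loss log),
#'   `config`, `val_idx`.
#' @export
ssfa_train <- function(labeled, unlabeled = list(), config = desk_config(),
                       init_predictor = NULL) {
  if (!length(labeled)) stop("labeled set is empty", call. = FALSE)
  check_items(labeled, TRUE, "labeled")
  check_items(unlabeled, FALSE, "unlabeled")
  n_val <- max(1L, floor(config$val_frac * length(labeled)))
  if (n_val >= length(labeled)) n_val <- length(labeled) - 1L
  val_idx <- if (n_val > 0) {
    local_seed(derive_seed(config$seeds[["data"]], 7L),
               sort(sample(seq_along(labeled), n_val)))
  } else integer(0)
  train_lab <- setdiff(seq_along(labeled), val_idx)

  if (is.null(init_predictor)) {
    init_predictor <- pretrain_supervised(labeled[train_lab], config)
  }

  spec <- network_spec(depth = config$depth,
                       base_channels = config$base_channels,
                       fusion = config$fusion, norm = config$norm)
  net1 <- build_network(spec, config$seeds[["net1"]])
  net2 <- build_network(spec, config$seeds[["net2"]])
  st1 <- sgd_state(net1$params)
  st2 <- sgd_state(net2$params)

  # items: labeled-train, then unlabeled, then labeled-val (val images get
  # FA maps too, but never contribute gradients)
  items <- c(lapply(train_lab, function(i) c(labeled[[i]], list(role = "labeled"))),
             lapply(unlabeled, function(it) c(it, list(role = "unlabeled"))),
             lapply(val_idx, function(i) c(labeled[[i]], list(role = "val"))))
  images <- lapply(items, `[[`, "image")
  A0s <- init_fa_maps(init_predictor, images, config$L)
  fa_states <- lapply(A0s, fa_state, k = config$k)

  trainable <- which(vapply(items, function(it) it$role != "val", logical(1)))
  steps <- list()
  history <- data.frame()
  best <- list(val = -Inf, epoch = 0L, p1 = NULL, p2 = NULL,
               d1 = NA_real_, d2 = NA_real_)
  data_seed <- derive_seed(config$seeds[["data"]], 202L)
  local_seed(data_seed, {
    for (ep in seq_len(config$max_epoch)) {
      lam <- lambda_schedule(ep, config$max_epoch, config$lambda_max)
      lr <- current_lr(config, ep)
      ord <- sample(trainable)
      for (batch in split(ord, ceiling(seq_along(ord) / config$batch))) {
        acc1 <- NULL; acc2 <- NULL
        n_lab <- 0L; n_unlab <- 0L
        sup_sum <- 0; unsup_sum <- 0
        g1_lab <- NULL; g2_lab <- NULL; g1_un <- NULL; g2_un <- NULL
        for (i in batch) {
          it <- items[[i]]
          op <- sample_aug(config)
          img <- apply_aug(it$image, op)
          fa <- apply_aug(fa_states[[i]]$current, op)
          f1 <- net_forward(net1, img, fa, keep_tape = TRUE)
          f2 <- net_forward(net2, img, fa, keep_tape = TRUE)
          if (it$role == "labeled") {
            y <- apply_aug(it$mask, op)
            l1 <- dice_loss(f1$prob, y); l2 <- dice_loss(f2$prob, y)
            sup_sum <- sup_sum + l1 + l2
            n_lab <- n_lab + 1L
            g1_lab <- add_grads(g1_lab,
                                net_backward(net1, f1, dice_loss_grad(f1$prob, y)))
            g2_lab <- add_grads(g2_lab,
                                net_backward(net2, f2, dice_loss_grad(f2$prob, y)))
          } else {
            yh1 <- f1$prob >= 0.5  # hard pseudo-labels, detached
            yh2 <- f2$prob >= 0.5
            l1 <- dice_loss(f1$prob, yh2); l2 <- dice_loss(f2$prob, yh1)
            unsup_sum <- unsup_sum + l1 + l2
            n_unlab <- n_unlab + 1L
            g1_un <- add_grads(g1_un,
                               net_backward(net1, f1, dice_loss_grad(f1$prob, yh2)))
            g2_un <- add_grads(g2_un,
                               net_backward(net2, f2, dice_loss_grad(f2$prob, yh1)))
          }
        }
        l_sup <- if (n_lab) sup_sum / n_lab else 0
        l_unsup <- if (n_unlab) unsup_sum / n_unlab else 0
        l_total <- l_sup + lam * l_unsup
        if (!is.finite(l_total)) {
          stop(sprintf("NaN loss at epoch %d (l_sup=%g, l_unsup=%g)",
                       ep, l_sup, l_unsup), call. = FALSE)
        }
        if (n_lab) {
          acc1 <- add_grads(acc1, scale_grads(g1_lab, 1 / n_lab))
          acc2 <- add_grads(acc2, scale_grads(g2_lab, 1 / n_lab))
        }
        if (n_unlab) {
          acc1 <- add_grads(acc1, scale_grads(g1_un, lam / n_unlab))
          acc2 <- add_grads(acc2, scale_grads(g2_un, lam / n_unlab))
        }
        st1 <- sgd_step(net1, acc1, st1, lr, config$momentum, config$weight_decay)
        st2 <- sgd_step(net2, acc2, st2, lr, config$momentum, config$weight_decay)
        steps[[length(steps) + 1L]] <-
          list(epoch = ep, lambda = lam, l_sup = l_sup, l_unsup = l_unsup,
               l_total = l_total)
      }
      # per-epoch attention-map refresh from a clean (un-augmented) forward
      for (i in seq_along(items)) {
        img <- items[[i]]$image
        cur <- fa_states[[i]]$current
        P1 <- net_forward(net1, img, cur)$prob >= 0.5
        P2 <- net_forward(net2, img, cur)$prob >= 0.5
        A_hat <- fa_map_from_predictions(P1, P2, config$L, config$rho)
        update_fa_map(fa_states[[i]], A_hat)
      }
      # held-out Dice per branch
      vd <- c(NA_real_, NA_real_)
      if (length(val_idx)) {
        vi <- which(vapply(items, function(it) it$role == "val", logical(1)))
        d1 <- d2 <- numeric(0)
        for (i in vi) {
          img <- items[[i]]$image
          y <- items[[i]]$mask
          cur <- fa_states[[i]]$current
          p1 <- net_forward(net1, img, cur)$prob >= 0.5
          p2 <- net_forward(net2, img, cur)$prob >= 0.5
          d1 <- c(d1, volumetric_metrics(p1, y)[["dice"]])
          d2 <- c(d2, volumetric_metrics(p2, y)[["dice"]])
        }
        vd <- c(mean(d1), mean(d2))
        if (mean(vd) > best$val) {
          best <- list(val = mean(vd), epoch = ep,
                       p1 = net1$params, p2 = net2$params,
                       d1 = vd[1], d2 = vd[2])
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, lambda = lam, lr = lr,
        l_sup = mean(vapply(steps[vapply(steps, function(s) s$epoch == ep,
                                         logical(1))],
                            `[[`, numeric(1), "l_sup")),
        val_dice1 = vd[1], val_dice2 = vd[2]))
    }
  })
  if (!is.null(best$p1)) {
    net1$params <- best$p1
    net2$params <- best$p2
    best_branch <- if (best$d2 > best$d1) 2L else 1L
    best_val <- max(best$d1, best$d2)
  } else {
    best_branch <- 1L
    best_val <- NA_real_
  }
  net1$trained <- TRUE
  net2$trained <- TRUE
  structure(list(predictor1 = net1, predictor2 = net2,
                 init_predictor = init_predictor,
                 fa_states = fa_states, best_branch = best_branch,
                 best_val_dice = best_val, history = history, steps = steps,
                 config = config, val_idx = val_idx),
            class = "ssfa_dual_state")
}

#' Two-stage inference
#'
#' For an unseen image: (0) initialize the FA map from the supervised
#' pretrained predictor (both TS channels from its prediction, DS zero);
#' (1) run both trained branches with the initial map and regenerate the
#' map from their two binarized predictions, blending with the configured
#' `k`; (2) rerun the better branch with the refined map and binarize at
#' 0.5.
#'
#' @param state A trained `ssfa_dual_state`.
#' @param image Grayscale matrix in `[0, 1]`.
#' @param init_predictor Predictor for the cold-start map; defaults to the
#'   one stored in `state`. If unavailable, a zero map is used with a
#'   warning.
#' @return Logical mask of the input's shape.
#' @export
two_stage_inference <- function(state, image, init_predictor = NULL) {
  stopifnot(inherits(state, "ssfa_dual_state"))
  cfg <- state$config
  init_predictor <- init_predictor %||% state$init_predictor
  hw <- dim(image)
  A0 <- if (is.null(init_predictor)) {
    warning("no init predictor available; starting from a zero FA map")
    zero_fa_map(hw[1], hw[2])
  } else {
    P0 <- predict_mask(init_predictor, image)
    ts <- ts_map(P0, cfg$L)
    compose_fa_map(ts, ts, matrix(0, hw[1], hw[2]))
  }
  P1 <- net_forward(state$predictor1, image, A0)$prob >= 0.5
  P2 <- net_forward(state$predictor2, image, A0)$prob >= 0.5
  A_hat <- fa_map_from_predictions(P1, P2, cfg$L, cfg$rho)
  A1 <- (1 - cfg$k) * A0 + cfg$k * A_hat
  net <- if (state$best_branch == 2L) state$predictor2 else state$predictor1
  net_forward(net, image, A1)$prob >= 0.5
}

#' @export
print.ssfa_dual_state <- function(x, ...) {
  cat(sprintf(
    "<dual training state: %d epochs, best branch %d (held-out Dice %.3f)>\n",
    nrow(x$history), x$best_branch, x$best_val_dice))
  invisible(x)
}
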