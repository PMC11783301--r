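# The Fracture-Attention Map: two thickness-sensitive (TS) channels, one
# difference-sensitive (DS) channel, composed per image and blended across
# epochs against the initial map.

FA_CHANNELS <- c("ts1", "ts2", "ds")

#' Thickness-sensitive attention map
#'
#' Builds a per-pixel attention map from a segmentation mask by eroding the
#' mask through a ladder of `L` distance thresholds and watching which
#' centerline segments disappear. For each level `l`, pixels of the mask
#' with distance value below `t_l` are deleted and the remainder is
#' re-skeletonized; a centerline pixel "fails" level `l` when no pixel of
#' the level-`l` skeleton lies within Chebyshev radius 1 of it. Each
#' centerline pixel scores `(number of failed levels) / L`, and the score
#' is propagated to full branch width by assigning every foreground pixel
#' the score of its nearest centerline pixel. Thin branches fail many
#' levels and score near 1; the thickest structures score near 0. Values
#' are multiples of `1/L` in `[0, 1]` and exactly 0 outside the mask.
#'
#' @param P Logical matrix (binary prediction or mask).
#' @param L Number of attention levels (default 10).
#' @return Numeric matrix in `[0, 1]`, same shape as `P`.
#' @export
ts_map <- function(P, L = 10L) {
  P <- as_mask(P)
  out <- matrix(0, nrow(P), ncol(P))
  # degenerate: no foreground, or no background (no finite thickness)
  if (!any(P) || all(P)) return(out)
  S <- skeletonize(P)
  dm <- distance_map(P, skeleton = S)
  D <- dm$pixels
  tl <- threshold_ladder(dm$dmin, dm$dmax, L)
  sk_idx <- which(S)
  fails <- integer(length(sk_idx))
  for (l in seq_len(L)) {
    Pl <- P & (D >= tl[l])
    if (any(Pl)) {
      Sl <- skeletonize(Pl)
      alive <- as_logical_mat(.dilate_cpp(as_int_mat(Sl), 1L))
      fails <- fails + !alive[sk_idx]
    } else {
      fails <- fails + 1L
    }
  }
  score <- fails / L
  # full-width reconstruction: each mask pixel inherits its nearest
  # centerline pixel's score
  ft <- feature_transform(S)
  near <- ft$nearest
  sk_score <- numeric(length(P))
  sk_score[sk_idx] <- score
  fg <- which(P)
  out[fg] <- sk_score[near[fg]]
  out
}

#' Difference-sensitive attention map
#'
#' Marks regions where two segmentation predictions genuinely disagree
#' about structure, while suppressing one-pixel boundary jitter. A
#' centerline pixel of one prediction is *mismatched* when the other
#' prediction's skeleton has no pixel within Euclidean radius `rho`.
#' A pixel of the symmetric difference `P1 XOR P2` is flagged when its
#' nearest centerline pixel (in the skeleton of whichever prediction
#' contains it) is mismatched; this covers disputed branches at full
#' width. Identical predictions give an identically zero map, and the
#' operation is symmetric in its arguments.
#'
#' @param P1,P2 Logical matrices of identical shape.
#' @param rho Skeleton matching tolerance in pixels (default 2).
#' @return Numeric 0/1 matrix of the same shape.
#' @export
ds_map <- function(P1, P2, rho = 2) {
  P1 <- as_mask(P1); P2 <- as_mask(P2)
  check_same_shape(P1, P2, "predictions")
  out <- matrix(0, nrow(P1), ncol(P1))
  sym <- xor(P1, P2)
  if (!any(sym)) return(out)
  S1 <- skeletonize(P1)
  S2 <- skeletonize(P2)
  flag_side <- function(only, S_self, S_other) {
    # pixels in `only` whose nearest own-skeleton pixel is > rho from the
    # other skeleton
    idx <- which(only)
    if (!length(idx)) return(integer(0))
    if (!any(S_self)) return(idx)  # no own structure at all: all disputed
    d_other <- edt_of(S_other)
    mism <- matrix(FALSE, nrow(out), ncol(out))
    mism[S_self] <- d_other[S_self] > rho
    ft <- feature_transform(S_self)
    idx[mism[ft$nearest[idx]]]
  }
  out[flag_side(P1 & !P2, S1, S2)] <- 1
  out[flag_side(P2 & !P1, S2, S1)] <- 1
  out
}

#' Compose a Fracture-Attention Map from its channels
#'
#' Stacks the two thickness-sensitive maps and the difference-sensitive
#' map into the fixed channel order `(ts1, ts2, ds)`.
#'
#' @param ts1,ts2 Thickness-sensitive maps (numeric matrices in `[0, 1]`).
#' @param ds Difference-sensitive map.
#' @return Numeric `H x W x 3` array with channel dimnames.
#' @export
compose_fa_map <- function(ts1, ts2, ds) {
  check_same_shape(ts1, ts2, "TS maps")
  check_same_shape(ts1, ds, "TS and DS maps")
  a <- array(c(ts1, ts2, ds), dim = c(dim(ts1), 3L),
             dimnames = list(NULL, NULL, FA_CHANNELS))
  if (min(a) < 0 || max(a) > 1) {
    stop("FA map channels must lie in [0, 1]", call. = FALSE)
  }
  a
}

#' Create per-image attention-map state
#'
#' Holds the initial map `A0`, the current map, and the update weight `k`
#' used to blend newly generated maps against the initial one.
#'
#' @param A0 Initial 3-channel FA map.
#' @param k Update weight in `[0, 1]`; `k = 0` freezes the map at `A0`,
#'   `k = 1` always adopts the freshly generated map.
#' @return An environment of class `ssfa_fa_state` with fields `A0`,
#'   `current`, `k`.
#' @export
fa_state <- function(A0, k) {
  if (k < 0 || k > 1) stop("update weight k must lie in [0, 1]", call. = FALSE)
  stopifnot(length(dim(A0)) == 3L, dim(A0)[3] == 3L)
  st <- new.env(parent = emptyenv())
  st$A0 <- A0
  st$current <- A0
  st$k <- k
  class(st) <- "ssfa_fa_state"
  st
}

#' Blend a freshly generated FA map into the state
#'
#' The current map after an update is always
#' `(1 - k) * A0 + k * A_hat`, a convex blend of the *initial* map and the
#' *latest* generated map -- the update is not recursive in the previous
#' current map. The result is stored as the state's current map and
#' returned.
#'
#' @param state An [fa_state()] object.
#' @param A_hat_r FA map generated from the current epoch's predictions.
#' @return The updated 3-channel FA map.
#' @export
update_fa_map <- function(state, A_hat_r) {
  stopifnot(inherits(state, "ssfa_fa_state"))
  if (!identical(dim(state$A0), dim(A_hat_r))) {
    stop("generated map shape differs from the initial map", call. = FALSE)
  }
  k <- state$k
  cur <- (1 - k) * state$A0 + k * A_hat_r
  state$current <- cur
  cur
}

# Build the 3-channel map from a pair of binary predictions.
fa_map_from_predictions <- function(P1, P2, L = 10L, rho = 2) {
  compose_fa_map(ts_map(P1, L), ts_map(P2, L), ds_map(P1, P2, rho))
}

#' Initial FA maps from a supervised predictor
#'
#' With only a single (supervised) prediction available per image, both TS
#' channels are built from that prediction and the DS channel is zero: a
#' disagreement map needs two predictions, which only exist once dual
#' training starts.
#'
#' @param predictor A trained single-branch predictor (see
#'   [pretrain_supervised()]).
#' @param images List of grayscale image matrices in `[0, 1]`.
#' @param L Attention levels.
#' @return List of `H x W x 3` FA maps, one per image.
#' @export
init_fa_maps <- function(predictor, images, L = 10L) {
  stopifnot(inherits(predictor, "ssfa_predictor"))
  if (!isTRUE(predictor$trained)) {
    stop("initial FA maps require a trained predictor", call. = FALSE)
  }
  lapply(images, function(img) {
    P <- predict_mask(predictor, img)
    ts <- ts_map(P, L)
    compose_fa_map(ts, ts, matrix(0, nrow(ts), ncol(ts)))
  })
}

zero_fa_map <- function(h, w) {
  array(0, dim = c(h, w, 3L), dimnames = list(NULL, NULL, FA_CHANNELS))
}
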