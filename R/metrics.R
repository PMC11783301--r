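# Topological and volumetric evaluation of binary segmentations.

#' Fracture Rate of a prediction against ground truth
#'
#' The Fracture Rate is the percentage of centerline edges of the ground
#' truth's topological graph that the prediction fails to cover. The
#' ground-truth mask is skeletonized and converted to a graph (spur-pruned,
#' see [skeleton_to_graph()]); the prediction is skeletonized and pruned the
#' same way. An edge counts as *fractured* when at least one pixel of its
#' middle segment -- the path with `min(delta, floor(len/3))` pixels
#' excluded at each end, since endpoint neighbourhoods legitimately shift
#' between skeletons -- has no predicted-skeleton pixel within Euclidean
#' distance `delta`. `FR = 100 * N_F / N_Y`.
#'
#' Matching is against the prediction's *skeleton*, not its raw
#' foreground: a thin fracture bridged by a blob of foreground would
#' otherwise be invisible.
#'
#' @param P Predicted binary mask.
#' @param Y Ground-truth binary mask (must contain foreground).
#' @param delta Matching tolerance in pixels (default 5).
#' @return Object of class `ssfa_fracture_report`: list with `n_edges`
#'   (N_Y), `n_fractured` (N_F), `fr` (percent), `fractured_edge_ids`,
#'   `per_edge` (logical verdict per ground-truth edge), `graph` (the
#'   ground-truth graph).
#' @export
#' @examples
#' ph <- generate_phantom(seed = 3, size = 96)
#' fracture_rate(ph$mask, ph$mask)$fr  # 0: perfect prediction
fracture_rate <- function(P, Y, delta = 5) {
  P <- as_mask(P); Y <- as_mask(Y)
  check_same_shape(P, Y, "prediction and ground truth")
  if (!any(Y)) stop("no ground-truth topology: Y is empty", call. = FALSE)
  gY <- skeleton_to_graph(skeletonize(Y))
  if (!length(gY$edges)) stop("no ground-truth topology: graph has no edges",
                              call. = FALSE)
  SP <- pruned_skeleton(P)
  dSP <- edt_of(SP)
  per_edge <- vapply(gY$edges, function(e) {
    mid <- edge_middle(e$path, delta)
    if (!nrow(mid)) return(FALSE)
    any(dSP[mid] > delta)
  }, logical(1))
  nF <- sum(per_edge)
  nY <- length(per_edge)
  structure(list(n_edges = nY, n_fractured = nF, fr = 100 * nF / nY,
                 fractured_edge_ids = which(per_edge), per_edge = per_edge,
                 graph = gY),
            class = "ssfa_fracture_report")
}

# Middle segment of an edge path: exclude min(delta, floor(n/3)) pixels at
# each end so short edges remain evaluable.
edge_middle <- function(path, delta) {
  n <- nrow(path)
  trim <- min(delta, floor(n / 3))
  path[(trim + 1):(n - trim), , drop = FALSE]
}

# Spur-pruned skeleton of a mask, as used for fracture matching.
pruned_skeleton <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  g <- skeleton_to_graph(skeletonize(mask))
  graph_skeleton(g, dim(mask))
}

#' @export
print.ssfa_fracture_report <- function(x, ...) {
  cat(sprintf("Fracture Rate: %.2f%% (%d of %d ground-truth edges fractured)\n",
              x$fr, x$n_fractured, x$n_edges))
  invisible(x)
}

#' Centerline Dice (clDice)
#'
#' Harmonic mean of topology precision and topology sensitivity:
#' `Tprec = |skel(P) intersect Y| / |skel(P)|`,
#' `Tsens = |skel(Y) intersect P| / |skel(Y)|`,
#' `clDice = 2 * Tprec * Tsens / (Tprec + Tsens)`. Raw (unpruned)
#' skeletons are used. Two empty masks score 1; exactly one empty mask
#' scores 0.
#'
#' @param P,Y Binary masks of identical shape.
#' @return clDice in `[0, 1]`.
#' @export
cl_dice <- function(P, Y) {
  P <- as_mask(P); Y <- as_mask(Y)
  check_same_shape(P, Y, "masks")
  if (!any(P) && !any(Y)) return(1)
  if (!any(P) || !any(Y)) return(0)
  sP <- skeletonize(P)
  sY <- skeletonize(Y)
  tprec <- sum(sP & Y) / sum(sP)
  tsens <- sum(sY & P) / sum(sY)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

#' Betti-number errors
#'
#' Betti numbers on the pixel grid with the standard duality pair:
#' foreground components are 8-connected (`beta0`), holes are 4-connected
#' background components minus one (`beta1`). The errors are the absolute
#' prediction-vs-truth differences and `beta = beta0_error + beta1_error`.
#'
#' @param P,Y Binary masks of identical shape.
#' @return Named numeric vector `c(beta, beta0, beta1)` of errors.
#' @export
betti_errors <- function(P, Y) {
  P <- as_mask(P); Y <- as_mask(Y)
  check_same_shape(P, Y, "masks")
  b <- function(m) {
    b0 <- if (any(m)) max(.label_cpp(as_int_mat(m), 8L)) else 0L
    # pad so the outer background is a single component
    pm <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    pm[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    b1 <- max(.label_cpp(as_int_mat(!pm), 4L)) - 1L
    c(b0, b1)
  }
  bp <- b(P); by <- b(Y)
  e0 <- abs(bp[1] - by[1])
  e1 <- abs(bp[2] - by[2])
  c(beta = e0 + e1, beta0 = e0, beta1 = e1)
}

#' Volumetric segmentation metrics
#'
#' Pixel accuracy, Dice and Jaccard on the foreground. Two empty masks
#' give Dice = Jaccard = 1.
#'
#' @param P,Y Binary masks of identical shape.
#' @return Named numeric vector `c(acc, dice, jaccard)`.
#' @export
volumetric_metrics <- function(P, Y) {
  P <- as_mask(P); Y <- as_mask(Y)
  check_same_shape(P, Y, "masks")
  inter <- sum(P & Y)
  uni <- sum(P | Y)
  acc <- mean(P == Y)
  if (sum(P) + sum(Y) == 0) return(c(acc = acc, dice = 1, jaccard = 1))
  dice <- 2 * inter / (sum(P) + sum(Y))
  jac <- if (uni == 0) 1 else inter / uni
  c(acc = acc, dice = dice, jaccard = jac)
}

#' Full metric report for one prediction
#'
#' Bundles the topological metrics (Fracture Rate, clDice, Betti errors)
#' and the volumetric metrics into one named list.
#'
#' @param P,Y Binary masks of identical shape; `Y` nonempty.
#' @param delta Fracture-matching tolerance in pixels.
#' @return Named list with `fr`, `cl_dice`, `beta`, `beta0`, `beta1`,
#'   `acc`, `dice`, `jaccard`.
#' @export
metric_report <- function(P, Y, delta = 5) {
  be <- betti_errors(P, Y)
  vm <- volumetric_metrics(P, Y)
  list(fr = fracture_rate(P, Y, delta)$fr,
       cl_dice = cl_dice(P, Y),
       beta = unname(be["beta"]), beta0 = unname(be["beta0"]),
       beta1 = unname(be["beta1"]),
       acc = unname(vm["acc"]), dice = unname(vm["dice"]),
       jaccard = unname(vm["jaccard"]))
}
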