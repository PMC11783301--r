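# Skeletons, distance maps and the attention threshold ladder.

#' Skeletonize a binary mask
#'
#' Thins the foreground to a one-pixel-wide medial representation using
#' iterative two-subcycle thinning. Connectivity of each 8-connected
#' foreground component is preserved; an empty mask yields an empty
#' skeleton. The operation is idempotent: skeletonizing a skeleton leaves
#' it unchanged.
#'
#' @param mask Logical matrix, `TRUE` on foreground.
#' @return Logical matrix of the same shape, `TRUE` on skeleton pixels.
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 40)
#' m[8:12, 5:35] <- TRUE
#' s <- skeletonize(m)
#' sum(s) < sum(m)
skeletonize <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  as_logical_mat(.thin_cpp(as_int_mat(mask)))
}

#' Euclidean distance map of a mask
#'
#' Exact Euclidean distance transform of the foreground: each foreground
#' pixel carries its distance to the nearest background pixel center, so a
#' foreground pixel adjacent to background (and an isolated foreground
#' pixel) has value 1; background is exactly 0. `dmin`/`dmax` are taken
#' over skeleton pixels only, because the attention ladder is built from
#' centerline thickness.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @param skeleton Optional precomputed skeleton of `mask`; computed when
#'   missing.
#' @return An object of class `ssfa_distance_map`: list with `pixels`
#'   (numeric matrix), `dmin`, `dmax`.
#' @export
distance_map <- function(mask, skeleton = NULL) {
  mask <- as_mask(mask)
  if (!any(mask)) {
    stop("distance_map is undefined for an empty mask (no dmin/dmax)",
         call. = FALSE)
  }
  d <- edt_of(!mask)
  d[!mask] <- 0
  if (is.null(skeleton)) skeleton <- skeletonize(mask)
  dsk <- d[skeleton]
  if (!length(dsk)) dsk <- d[mask]
  structure(list(pixels = d, dmin = min(dsk), dmax = max(dsk)),
            class = "ssfa_distance_map")
}

# Distance of every pixel to the nearest TRUE site. All-FALSE sites give Inf.
edt_of <- function(sites) {
  if (!any(sites)) {
    return(matrix(Inf, nrow(sites), ncol(sites)))
  }
  .edt_cpp(as_int_mat(sites))$dist
}

# Distance + 1-based linear index of the nearest TRUE site per pixel.
feature_transform <- function(sites) {
  stopifnot(any(sites))
  .edt_cpp(as_int_mat(sites))
}

#' Attention-level threshold ladder
#'
#' Distance thresholds for the `L` attention levels of a
#' thickness-sensitive map, linearly interpolated between the minimum and
#' maximum centerline distance: `t_l = dmin + l * (dmax - dmin) / L` for
#' `l = 1, ..., L`. When `dmax == dmin` (uniform thickness) all levels
#' coincide and downstream maps collapse to a single occupied level.
#'
#' @param dmin,dmax Centerline distance extremes, `dmax >= dmin > 0`.
#' @param L Number of attention levels (default 10).
#' @return Numeric vector of length `L`, non-decreasing, ending at `dmax`.
#' @export
#' @examples
#' threshold_ladder(1, 11, 10)  # 2, 3, ..., 11
threshold_ladder <- function(dmin, dmax, L = 10L) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (dmax < dmin) stop("dmax must be >= dmin", call. = FALSE)
  if (dmin <= 0) stop("dmin must be > 0", call. = FALSE)
  dmin + seq_len(L) * (dmax - dmin) / L
}
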