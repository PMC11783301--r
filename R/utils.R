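# Shared helpers: seeding, mask coercion, small assertions.
#
# Coordinates are (row, col), 1-based in R, top-left origin. All randomness
# flows through `local_seed()` so that no function touches the global RNG
# state observably.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the Mersenne-Twister generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a child seed from a base seed and a stream label; keeps derived
# seeds inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) * 48271 + 111 * stream) %% 2147483629
  as.integer(x + 1)
}

#' Coerce to a binary mask
#'
#' Validates and converts a numeric or logical matrix to the package's
#' mask representation: a logical matrix, `TRUE` on foreground.
#'
#' @param x Matrix-like object; numeric values are thresholded at > 0.5.
#' @return Logical matrix.
#' @export
as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (!is.matrix(x)) stop("mask must be a matrix", call. = FALSE)
  m <- x > 0.5
  storage.mode(m) <- "logical"
  m
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("%s must have identical shape (%s vs %s)", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# logical matrix from a 0/1 integer matrix returned by C++ kernels
as_logical_mat <- function(m) {
  out <- m != 0L
  dim(out) <- dim(m)
  out
}

# integer 0/1 matrix for the C++ kernels
as_int_mat <- function(mask) {
  out <- mask + 0L
  storage.mode(out) <- "integer"
  out
}
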