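# Synthetic tubular phantoms: random branching centerline trees swept with
# discs of smoothly varying radius, rendered to a noisy grayscale image
# with optional low-contrast (semantically ambiguous) regions. Phantoms
# carry their planted centerlines and expected topology, so topology
# metrics can be checked against a known answer without external data.

#' Generate a tubular phantom
#'
#' Plants `n_trees` random branching centerline trees (a curvature-bounded
#' trunk random walk, with child branches spawned at interior points) and
#' sweeps a disc of smoothly varying radius (linear taper plus sinusoidal
#' modulation, clamped to `radius_range`) along each centerline. The image
#' is a smoothed, brightened rendering of the mask plus Gaussian noise,
#' clipped to `[0, 1]`; `n_ambiguity` circular regions get their local
#' contrast multiplied by a factor in `[0.2, 0.6]` (the mask is not
#' touched), creating the low-contrast zones where segmentation
#' predictions typically disagree. Regeneration with the same arguments is
#' bit-identical, and the global RNG stream is left undisturbed.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param size Image side in pixels (>= 64).
#' @param n_trees Number of planted trees.
#' @param radius_range Numeric `(min, max)` tube radius in pixels, min >= 1.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_ambiguity Number of low-contrast regions (default 2).
#' @return Object of class `ssfa_phantom`: list with `image` (matrix in
#'   `[0,1]`), `mask` (logical matrix), `planted_graph` (list of branches,
#'   each with `path` n-x-2 float matrix and `radius` vector),
#'   `planted_edge_count` (expected topological edge count: branches plus
#'   interior attachment splits), `seed`.
#' @export
#' @examples
#' ph <- generate_phantom(seed = 1, size = 96, n_trees = 1)
#' range(ph$image)
#' sum(ph$mask) > 0
generate_phantom <- function(seed, size = 128L, n_trees = 3L,
                             radius_range = c(2, 6), noise_sd = 0.05,
                             n_ambiguity = 2L) {
  if (size < 64) stop("size must be >= 64", call. = FALSE)
  if (radius_range[1] < 1) stop("minimum radius must be >= 1", call. = FALSE)
  rmax <- radius_range[2]
  margin <- ceiling(rmax) + 2
  if (size - 2 * margin < 24) {
    stop("placement failure: image too small for the requested tree radii",
         call. = FALSE)
  }
  local_seed(seed, {
    branches <- list()
    n_attach <- 0L
    for (tr in seq_len(n_trees)) {
      tree <- grow_tree(size, margin, radius_range)
      branches <- c(branches, tree$branches)
      n_attach <- n_attach + tree$n_attach
    }
    mask <- rasterize_branches(branches, size)
    img <- 0.15 + 0.65 * gaussian_blur(mask + 0, 1.0)
    # low-contrast regions: shrink deviation from background level
    if (n_ambiguity > 0) {
      for (i in seq_len(n_ambiguity)) {
        cr <- runif(1, margin, size - margin)
        cc <- runif(1, margin, size - margin)
        rad <- runif(1, size / 16, size / 8)
        fac <- runif(1, 0.2, 0.6)
        rows <- matrix(seq_len(size), size, size)
        cols <- t(rows)
        inside <- (rows - cr)^2 + (cols - cc)^2 <= rad^2
        img[inside] <- 0.15 + (img[inside] - 0.15) * fac
      }
    }
    img <- img + matrix(rnorm(size * size, 0, noise_sd), size, size)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask, planted_graph = branches,
                   planted_edge_count = length(branches) + n_attach,
                   seed = as.integer(seed)),
              class = "ssfa_phantom")
  })
}

# One branching tree: trunk random walk + children attached at interior
# trunk points. Returns branches and the number of interior attachments
# (each attachment splits its parent, adding one expected graph edge).
grow_tree <- function(size, margin, radius_range) {
  rmin <- radius_range[1]; rmax <- radius_range[2]
  lo <- margin + 1; hi <- size - margin
  walk_branch <- function(r0c0, ang, n_steps, rad_start, rad_end) {
    pr <- numeric(n_steps); pc <- numeric(n_steps)
    r <- r0c0[1]; c <- r0c0[2]
    phase <- runif(1, 0, 2 * pi)
    freq <- runif(1, 1, 3)
    rad <- numeric(n_steps)
    i <- 0L
    while (i < n_steps) {
      i <- i + 1L
      pr[i] <- r; pc[i] <- c
      t01 <- (i - 1) / max(1, n_steps - 1)
      rr <- rad_start + (rad_end - rad_start) * t01 +
        0.15 * rad_start * sin(2 * pi * freq * t01 + phase)
      rad[i] <- min(max(rr, rmin), rmax)
      ang <- ang + runif(1, -0.08, 0.08)
      # steer back toward the field center when close to the boundary, so
      # trunks reach their planted length instead of escaping
      near <- 1.8 * (lo - 1)
      if (r < lo + near || r > hi - near || c < lo + near || c > hi - near) {
        target <- atan2((lo + hi) / 2 - r, (lo + hi) / 2 - c)
        d <- atan2(sin(target - ang), cos(target - ang))
        ang <- ang + sign(d) * min(abs(d), 0.12)
      }
      r <- r + sin(ang); c <- c + cos(ang)
      if (r < lo || r > hi || c < lo || c > hi) break
    }
    list(path = cbind(row = pr[seq_len(i)], col = pc[seq_len(i)]),
         radius = rad[seq_len(i)], ang = ang)
  }
  # trunk
  for (attempt in 1:25) {
    start <- c(runif(1, lo, hi), runif(1, lo, hi))
    ang <- runif(1, 0, 2 * pi)
    len <- round(size * runif(1, 0.5, 0.8))
    r0 <- runif(1, 0.65, 1) * rmax
    r1 <- runif(1, 1, 1.6) * rmin
    trunk <- walk_branch(start, ang, len, r0, r1)
    if (nrow(trunk$path) >= 30) break
    if (attempt == 25) {
      stop("placement failure: could not fit a trunk of usable length",
           call. = FALSE)
    }
  }
  branches <- list(list(path = trunk$path, radius = trunk$radius))
  n_attach <- 0L
  n <- nrow(trunk$path)
  # children spawn from interior trunk points, away from the trunk ends
  p_child <- 0.012
  interior <- seq(from = 15, to = n - 15)
  if (length(interior) > 1) {
    for (i in interior) {
      if (runif(1) < p_child) {
        side <- sample(c(-1, 1), 1)
        cang <- atan2(trunk$path[min(i + 1, n), 1] - trunk$path[i, 1],
                      trunk$path[min(i + 1, n), 2] - trunk$path[i, 2]) +
          side * runif(1, 0.6, 1.2)
        clen <- round(runif(1, 0.3, 0.6) * n)
        cr0 <- max(rmin, 0.7 * trunk$radius[i])
        child <- walk_branch(trunk$path[i, ], cang, clen, cr0,
                             max(rmin, 0.5 * cr0))
        if (nrow(child$path) >= 22) {
          branches[[length(branches) + 1L]] <-
            list(path = child$path, radius = child$radius)
          n_attach <- n_attach + 1L
        }
      }
    }
  }
  list(branches = branches, n_attach = n_attach)
}

rasterize_branches <- function(branches, size) {
  mask <- matrix(FALSE, size, size)
  for (b in branches) {
    p <- b$path
    for (i in seq_len(nrow(p))) {
      rad <- b$radius[i]
      r0 <- max(1L, floor(p[i, 1] - rad)); r1 <- min(size, ceiling(p[i, 1] + rad))
      c0 <- max(1L, floor(p[i, 2] - rad)); c1 <- min(size, ceiling(p[i, 2] + rad))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - p[i, 1])^2, (cc - p[i, 2])^2, `+`)
      mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
    }
  }
  mask
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x) {  # along rows of a matrix (each column filtered)
    n <- nrow(x)
    pad <- rbind(x[rep(1, hw), , drop = FALSE], x,
                 x[rep(n, hw), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + n - 1), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Break edges of a tubular mask
#'
#' Interrupts `m` randomly chosen graph edges of a mask with an
#' all-background gap of `gap_px` centerline pixels centered on each
#' chosen edge's path midpoint. The full tube width around the gap
#' centerline is cleared (each foreground pixel is assigned to its nearest
#' skeleton pixel; pixels assigned to the gap window are deleted); no
#' other pixels are modified. Only edges long enough to keep their middle
#' segment detectable are eligible: path length must exceed
#' `gap_px + 2 * delta`.
#'
#' @param mask Logical mask.
#' @param graph Topological graph extracted from `mask` (see
#'   [skeleton_to_graph()]); computed when `NULL`.
#' @param m Number of edges to break; `0` is a no-op.
#' @param gap_px Gap length along the centerline, in pixels.
#' @param seed Integer seed for the choice of edges.
#' @param delta Tolerance used for the eligibility margin (default 5).
#' @return List with `mask` (the broken mask) and `broken` (ids of the
#'   interrupted edges in `graph`).
#' @export
inject_fractures <- function(mask, graph = NULL, m, gap_px, seed,
                             delta = 5) {
  mask <- as_mask(mask)
  if (is.null(graph)) graph <- skeleton_to_graph(skeletonize(mask))
  if (m == 0) return(list(mask = mask, broken = integer(0)))
  lens <- vapply(graph$edges, function(e) nrow(e$path), integer(1))
  eligible <- which(lens > gap_px + 2 * delta)
  if (m > length(eligible)) {
    stop(sprintf(
      "insufficient eligible edges: requested %d, only %d edges longer than %d px",
      m, length(eligible), gap_px + 2 * delta), call. = FALSE)
  }
  chosen <- local_seed(seed, sort(sample(eligible, m)))
  S <- skeletonize(mask)
  ft <- feature_transform(S)
  in_window <- logical(length(mask))
  for (id in chosen) {
    path <- graph$edges[[id]]$path
    n <- nrow(path)
    mid <- (n + 1) %/% 2
    i0 <- mid - (gap_px - 1) %/% 2
    i1 <- i0 + gap_px - 1
    win <- path[max(1, i0):min(n, i1), , drop = FALSE]
    in_window[(win[, 2] - 1L) * nrow(mask) + win[, 1]] <- TRUE
  }
  fg <- which(mask)
  kill <- fg[in_window[ft$nearest[fg]]]
  out <- mask
  out[kill] <- FALSE
  list(mask = out, broken = chosen)
}

#' Write a synthetic dataset to disk
#'
#' Generates labeled, unlabeled and test phantoms and writes them in the
#' directory layout the training tools consume:
#' `labeled/img_NNN`, `labeled/mask_NNN`, `unlabeled/img_NNN`,
#' `test/img_NNN`, `test/mask_NNN`, plus a `manifest.json` listing every
#' file with its role. Rerunning with identical arguments reproduces
#' identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_labeled,n_unlabeled,n_test Image counts per role.
#' @param seed Integer seed.
#' @param size,n_trees,noise_sd Phantom generator settings.
#' @param format `"pgm"` (binary portable graymap) or `"tif"`
#'   (uncompressed grayscale TIFF).
#' @return The manifest, invisibly (also written as JSON).
#' @export
make_dataset <- function(out_dir, n_labeled, n_unlabeled, n_test, seed,
                         size = 128L, n_trees = 3L, noise_sd = 0.05,
                         format = c("pgm", "tif")) {
  format <- match.arg(format)
  stopifnot(n_labeled >= 0, n_unlabeled >= 0, n_test >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roles <- c(rep("labeled", n_labeled), rep("unlabeled", n_unlabeled),
             rep("test", n_test))
  for (d in unique(roles)) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  entries <- list()
  counters <- c(labeled = 0L, unlabeled = 0L, test = 0L)
  for (i in seq_along(roles)) {
    role <- roles[i]
    counters[role] <- counters[role] + 1L
    ph <- generate_phantom(derive_seed(seed, i), size = size,
                           n_trees = n_trees, noise_sd = noise_sd)
    stem <- sprintf("%s_%03d", role, counters[role])
    img_file <- file.path(role, paste0("img_", stem, ".", format))
    write_image(ph$image, file.path(out_dir, img_file))
    entry <- list(role = role, image = img_file)
    if (role != "unlabeled") {
      mask_file <- file.path(role, paste0("mask_", stem, ".", format))
      write_mask(ph$mask, file.path(out_dir, mask_file))
      entry$mask <- mask_file
    }
    entries[[i]] <- entry
  }
  manifest <- list(generator = "ssfa::make_dataset", seed = as.integer(seed),
                   size = as.integer(size), n_trees = as.integer(n_trees),
                   noise_sd = noise_sd, format = format,
                   counts = list(labeled = n_labeled,
                                 unlabeled = n_unlabeled, n_test = n_test),
                   entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Standard desk-scale synthetic dataset, in memory
#'
#' The labeled/unlabeled/test split used throughout the desk-scale
#' experiments: 64x64 phantoms with two trees of radius 1.5-5 px, 8
#' labeled, 32 unlabeled and 8 test images by default. Each item is a
#' list with `image` and (except unlabeled) `mask`.
#'
#' @param seed Integer seed; per-image seeds are derived from it.
#' @param n_labeled,n_unlabeled,n_test Split sizes.
#' @param size Image side (default 64).
#' @return List with elements `labeled`, `unlabeled`, `test`.
#' @export
desk_dataset <- function(seed, n_labeled = 8L, n_unlabeled = 32L,
                         n_test = 8L, size = 64L) {
  gen <- function(n, offset) {
    lapply(seq_len(n), function(i) {
      ph <- generate_phantom(derive_seed(seed, offset + i), size = size,
                            n_trees = 2L, radius_range = c(1.5, 5))
      list(image = ph$image, mask = ph$mask)
    })
  }
  list(labeled = gen(n_labeled, 0L),
       unlabeled = lapply(gen(n_unlabeled, 1000L), function(it) {
         it$mask <- NULL
         it
       }),
       test = gen(n_test, 2000L))
}

#' @export
print.ssfa_phantom <- function(x, ...) {
  cat(sprintf(
    "<tubular phantom %dx%d: %d branches (%d expected edges), %d fg px, seed %d>\n",
    nrow(x$mask), ncol(x$mask), length(x$planted_graph),
    x$planted_edge_count, sum(x$mask), x$seed))
  invisible(x)
}
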