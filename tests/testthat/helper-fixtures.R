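# Fixtures are generated in code: simple geometric masks with known
# topology, phantom-backed training items, and a brute-force fracture
# oracle independent of the distance-transform implementation.

ribbon_mask <- function(h = 32, w = 100, rows = 14:18, cols = 5:95) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# several disjoint horizontal ribbons in one mask
multi_ribbon_mask <- function(widths, h = NULL, w = 120, gap = 8) {
  need <- sum(widths) + gap * (length(widths) + 1)
  h <- max(h %||% 0, need)
  m <- matrix(FALSE, h, w)
  top <- gap
  centers <- integer(length(widths))
  for (i in seq_along(widths)) {
    m[top + seq_len(widths[i]), 10:(w - 10)] <- TRUE
    centers[i] <- top + ceiling(widths[i] / 2)
    top <- top + widths[i] + gap
  }
  attr(m, "centers") <- centers
  m
}

annulus_mask <- function(size = 48, r_in = 10, r_out = 16) {
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  d2 >= r_in^2 & d2 <= r_out^2
}

cross_mask <- function(size = 41) {
  m <- matrix(FALSE, size, size)
  mid <- (size + 1) %/% 2
  m[mid, 5:(size - 4)] <- TRUE
  m[5:(size - 4), mid] <- TRUE
  m
}

phantom_items <- function(n, seed0, size = 64, n_trees = 2,
                          radius_range = c(1.5, 5)) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(seed0 + i, size = size, n_trees = n_trees,
                          radius_range = radius_range)
    list(image = ph$image, mask = ph$mask)
  })
}

# Brute-force fracture verdicts: for every middle-segment pixel of every
# ground-truth edge, scan all predicted-skeleton pixels for one within
# Euclidean distance delta. No distance transform involved.
oracle_fracture_verdicts <- function(P, Y, delta = 5) {
  gY <- skeleton_to_graph(skeletonize(Y))
  SP <- ssfa:::pruned_skeleton(P)
  sp <- which(SP, arr.ind = TRUE)
  vapply(gY$edges, function(e) {
    n <- nrow(e$path)
    trim <- min(delta, floor(n / 3))
    mid <- e$path[(trim + 1):(n - trim), , drop = FALSE]
    if (!nrow(sp)) return(TRUE)
    for (i in seq_len(nrow(mid))) {
      d2 <- (sp[, 1] - mid[i, 1])^2 + (sp[, 2] - mid[i, 2])^2
      if (min(d2) > delta^2) return(TRUE)
    }
    FALSE
  }, logical(1))
}

digest_bytes <- function(raw) paste(as.character(raw), collapse = "")

tiny_train_config <- function(...) {
  desk_config(max_epoch = 3L, init_epochs = 2L, base_channels = 4L,
              depth = 2L, batch = 4L, ...)
}
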