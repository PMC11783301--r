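# Skeleton -> topological graph. Nodes are junction/endpoint pixel
# clusters, edges carry the ordered 8-connected centerline path between
# them. Short terminal spurs (skeletonization artifacts) are pruned and
# degenerate micro-edges merged before the graph is reported, identically
# for predictions and ground truth, so edge counts are comparable.

NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Convert a skeleton to a topological graph
#'
#' Pixels with a number of skeleton neighbours different from 2
#' (8-connectivity) are node pixels; adjacent node pixels are clustered
#' into a single node. Edges trace the degree-2 chains between node
#' clusters; an isolated cycle (no node pixel at all) becomes one
#' self-loop edge anchored at an arbitrary articulation node. Terminal
#' spurs shorter than `prune_spur` pixels are removed iteratively, and
#' surviving edges whose path is shorter than `min_edge` pixels are
#' contracted into their incident node and never counted.
#'
#' @param skeleton Logical matrix, one-pixel-wide skeleton.
#' @param prune_spur Remove endpoint-terminated branches shorter than this
#'   many pixels (default 5; `0` disables pruning).
#' @param min_edge Contract edges with paths shorter than this many pixels
#'   (default 3).
#' @return Object of class `ssfa_topo_graph`: list with `nodes` (data.frame
#'   `id`, `row`, `col`, `kind`) and `edges` (list of `id`, `a`, `b`,
#'   `path` n-x-2 matrix of (row, col)).
#' @export
skeleton_to_graph <- function(skeleton, prune_spur = 5L, min_edge = 3L) {
  skeleton <- as_mask(skeleton)
  g <- trace_graph(skeleton)
  g <- prune_graph(g, prune_spur = prune_spur, min_edge = min_edge)
  g
}

empty_graph <- function() {
  structure(list(
    nodes = data.frame(id = integer(0), row = integer(0), col = integer(0),
                       kind = character(0), stringsAsFactors = FALSE),
    edges = list()
  ), class = "ssfa_topo_graph")
}

trace_graph <- function(skeleton) {
  H <- nrow(skeleton); W <- ncol(skeleton)
  if (!any(skeleton)) return(empty_graph())
  cnt <- .neighbor_count_cpp(as_int_mat(skeleton))
  node_px <- skeleton & (cnt != 2L)
  # cluster adjacent node pixels
  node_id <- matrix(0L, H, W)
  n_nodes <- 0L
  node_rows <- integer(0); node_cols <- integer(0)
  if (any(node_px)) {
    lab <- .label_cpp(as_int_mat(node_px), 8L)
    n_nodes <- max(lab)
    node_id <- lab
    for (i in seq_len(n_nodes)) {
      idx <- which(lab == i)
      rr <- ((idx - 1L) %% H) + 1L
      cc <- ((idx - 1L) %/% H) + 1L
      # representative pixel: cluster member closest to the centroid
      j <- which.min((rr - mean(rr))^2 + (cc - mean(cc))^2)
      node_rows[i] <- rr[j]; node_cols[i] <- cc[j]
    }
  }
  visited <- matrix(FALSE, H, W)  # chain pixels already traced
  edges <- list()
  add_edge <- function(a, b, path) {
    edges[[length(edges) + 1L]] <<- list(id = length(edges) + 1L,
                                         a = a, b = b, path = path)
  }
  nbrs <- function(r, c) {
    rr <- r + NB8[, 1L]; cc <- c + NB8[, 2L]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    cbind(rr[ok], cc[ok])
  }
  walk <- function(start_r, start_c, r, c) {
    # start at node pixel (start_r, start_c), step into chain pixel (r, c)
    path_r <- c(start_r, r); path_c <- c(start_c, c)
    visited[r, c] <<- TRUE
    prev_r <- start_r; prev_c <- start_c
    repeat {
      nb <- nbrs(r, c)
      keep <- skeleton[nb] & !(nb[, 1L] == prev_r & nb[, 2L] == prev_c)
      nb <- nb[keep, , drop = FALSE]
      if (!nrow(nb)) {  # dead end: terminate at current pixel
        return(list(end = 0L, r = r, c = c, path = cbind(path_r, path_c)))
      }
      is_node <- node_id[nb] > 0L
      if (any(is_node)) {
        # prefer a node pixel that is not the start pixel itself
        cand <- nb[is_node, , drop = FALSE]
        not_start <- !(cand[, 1L] == start_r & cand[, 2L] == start_c)
        pick <- if (any(not_start)) cand[which(not_start)[1L], ] else cand[1L, ]
        path_r <- c(path_r, pick[1L]); path_c <- c(path_c, pick[2L])
        return(list(end = node_id[pick[1L], pick[2L]], r = pick[1L],
                    c = pick[2L], path = cbind(path_r, path_c)))
      }
      unvis <- !visited[nb]
      if (!any(unvis)) {  # closed onto an already traced chain
        return(list(end = 0L, r = r, c = c, path = cbind(path_r, path_c)))
      }
      nxt <- nb[which(unvis)[1L], ]
      prev_r <- r; prev_c <- c
      r <- nxt[1L]; c <- nxt[2L]
      visited[r, c] <<- TRUE
      path_r <- c(path_r, r); path_c <- c(path_c, c)
    }
  }
  new_node <- function(r, c) {
    n_nodes <<- n_nodes + 1L
    node_rows[n_nodes] <<- r; node_cols[n_nodes] <<- c
    node_id[r, c] <<- n_nodes
    n_nodes
  }
  if (n_nodes > 0L) {
    npx <- which(node_id > 0L)
    npx_r <- ((npx - 1L) %% H) + 1L
    npx_c <- ((npx - 1L) %/% H) + 1L
    done_pairs <- character(0)
    for (i in seq_along(npx)) {
      r <- npx_r[i]; c <- npx_c[i]
      a <- node_id[r, c]
      nb <- nbrs(r, c)
      for (j in seq_len(nrow(nb))) {
        r2 <- nb[j, 1L]; c2 <- nb[j, 2L]
        if (!skeleton[r2, c2]) next
        b <- node_id[r2, c2]
        if (b > 0L) {
          # direct node-to-node adjacency across clusters
          if (a != b) {
            key <- paste(min(r, r2), min(c, c2), max(r, r2), max(c, c2))
            if (!(key %in% done_pairs)) {
              done_pairs <- c(done_pairs, key)
              add_edge(a, b, cbind(c(r, r2), c(c, c2)))
            }
          }
        } else if (!visited[r2, c2]) {
          w <- walk(r, c, r2, c2)
          endn <- w$end
          if (endn == 0L) endn <- new_node(w$r, w$c)
          path <- w$path
          colnames(path) <- c("row", "col")
          add_edge(a, endn, path)
        }
      }
    }
  }
  # leftover unvisited degree-2 chains are isolated cycles
  left <- skeleton & !visited & node_id == 0L
  while (any(left)) {
    idx <- which(left)[1L]
    r <- ((idx - 1L) %% H) + 1L
    c <- ((idx - 1L) %/% H) + 1L
    a <- new_node(r, c)
    nb <- nbrs(r, c)
    nb <- nb[skeleton[nb], , drop = FALSE]
    if (nrow(nb) == 0L) {
      left[r, c] <- FALSE
      next
    }
    w <- walk(r, c, nb[1L, 1L], nb[1L, 2L])
    endn <- w$end
    path <- w$path
    colnames(path) <- c("row", "col")
    if (endn == 0L) {
      # open dead end (should not normally occur); close as its own node
      endn <- new_node(w$r, w$c)
    }
    add_edge(a, endn, path)
    left <- skeleton & !visited & node_id == 0L
  }
  nodes <- data.frame(id = seq_len(n_nodes),
                      row = node_rows[seq_len(n_nodes)],
                      col = node_cols[seq_len(n_nodes)],
                      kind = "junction", stringsAsFactors = FALSE)
  g <- structure(list(nodes = nodes, edges = edges), class = "ssfa_topo_graph")
  set_node_kinds(g)
}

node_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    deg[e$a] <- deg[e$a] + 1L
    deg[e$b] <- deg[e$b] + 1L
  }
  deg
}

set_node_kinds <- function(g) {
  deg <- node_degrees(g)
  g$nodes$kind <- ifelse(deg <= 1L, "endpoint", "junction")
  g
}

prune_graph <- function(g, prune_spur = 5L, min_edge = 3L) {
  repeat {
    if (!length(g$edges)) break
    deg <- node_degrees(g)
    lens <- vapply(g$edges, function(e) nrow(e$path), integer(1))
    spur <- vapply(g$edges, function(e) {
      (deg[e$a] == 1L || deg[e$b] == 1L) && e$a != e$b
    }, logical(1)) & lens < prune_spur
    # never remove a component entirely: keep an edge whose both endpoints
    # are degree-1 (an isolated segment), however short
    isolated <- vapply(g$edges, function(e) {
      deg[e$a] == 1L && deg[e$b] == 1L
    }, logical(1))
    spur <- spur & !isolated
    if (!any(spur)) break
    g$edges <- g$edges[!spur]
  }
  # contract sub-minimal edges between distinct nodes
  if (length(g$edges)) {
    keep <- logical(length(g$edges))
    remap <- seq_len(nrow(g$nodes))
    resolve <- function(i) {
      while (remap[i] != i) i <- remap[i]
      i
    }
    lens <- vapply(g$edges, function(e) nrow(e$path), integer(1))
    for (i in seq_along(g$edges)) {
      e <- g$edges[[i]]
      a <- resolve(e$a); b <- resolve(e$b)
      if (lens[i] < min_edge && a != b) {
        remap[b] <- a
        keep[i] <- FALSE
      } else {
        keep[i] <- TRUE
      }
    }
    g$edges <- g$edges[keep]
    g$edges <- lapply(g$edges, function(e) {
      e$a <- resolve(e$a); e$b <- resolve(e$b); e
    })
  }
  # splice out degree-2 pass-through nodes left by pruning: their two
  # incident edges merge into one continuous edge
  repeat {
    if (length(g$edges) < 2L) break
    deg <- node_degrees(g)
    ea <- vapply(g$edges, `[[`, integer(1), "a")
    eb <- vapply(g$edges, `[[`, integer(1), "b")
    spliced <- FALSE
    for (v in which(deg == 2L)) {
      inc <- which(ea == v | eb == v)
      if (length(inc) != 2L) next  # a self-loop at v counts twice: keep
      e1 <- g$edges[[inc[1]]]; e2 <- g$edges[[inc[2]]]
      # orient e1 to end at v and e2 to start at v
      if (e1$a == v) { e1$path <- e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
                       e1$a <- e1$b }
      if (e2$b == v) { e2$path <- e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
                       e2$b <- e2$a }
      merged <- list(id = e1$id, a = e1$a, b = e2$b,
                     path = rbind(e1$path, e2$path[-1L, , drop = FALSE]))
      g$edges[[inc[1]]] <- merged
      g$edges <- g$edges[-inc[2]]
      spliced <- TRUE
      break
    }
    if (!spliced) break
  }
  # drop orphan nodes, renumber
  used <- sort(unique(c(vapply(g$edges, `[[`, integer(1), "a"),
                        vapply(g$edges, `[[`, integer(1), "b"))))
  if (length(used)) {
    lut <- integer(nrow(g$nodes))
    lut[used] <- seq_along(used)
    g$nodes <- g$nodes[used, , drop = FALSE]
    g$nodes$id <- seq_along(used)
    rownames(g$nodes) <- NULL
    g$edges <- lapply(seq_along(g$edges), function(i) {
      e <- g$edges[[i]]
      e$id <- i
      e$a <- lut[e$a]; e$b <- lut[e$b]
      e
    })
  } else {
    g <- empty_graph()
  }
  set_node_kinds(g)
}

#' Number of edges of a topological graph
#' @param g An `ssfa_topo_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) length(g$edges)

# Pixels covered by the pruned graph (node pixels + edge paths), as a mask.
graph_skeleton <- function(g, dim_hw) {
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  for (e in g$edges) m[e$path] <- TRUE
  if (nrow(g$nodes)) m[cbind(g$nodes$row, g$nodes$col)] <- TRUE
  m
}

#' @export
print.ssfa_topo_graph <- function(x, ...) {
  cat(sprintf("<topological graph: %d nodes (%d endpoints), %d edges>\n",
              nrow(x$nodes), sum(x$nodes$kind == "endpoint"),
              length(x$edges)))
  invisible(x)
}
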