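# Discretize each cell into exactly n points. Neuron skeletons are
# sampled at even arclength steps radially from the soma (the step is
# found by binary search); meshes are subsampled evenly by vertex
# order; mask outlines are traced and sampled at equal perimeter
# spacing.

new_point_cloud <- function(points, cell_id, source, provenance = NULL,
                            step = NA_real_) {
  structure(list(cell_id = cell_id, points = points, n = nrow(points),
                 source = source, provenance = provenance, step = step),
            class = "point_cloud")
}

#' @exportS3Method base::print
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> cell '%s': %d points (%dD, %s)\n",
              x$cell_id, x$n, ncol(x$points), x$source))
  invisible(x)
}

# Walk the tree depth-first from the root (file order among siblings),
# emitting a point whenever the arclength accumulated since the last
# emitted point on the current root-to-leaf path reaches `step`.
# Residual arclength carries across branch points, so samples sit at
# geodesic radii 0, step, 2*step, ... from the soma. Returns the
# sample coordinates plus, per sample, the index of the previous
# sample on its path (the chain used for the geodesic graph).
swc_walk_sample <- function(tree, step) {
  pos <- match(tree$parent, tree$id)
  children <- vector("list", nrow(tree))
  for (i in rev(which(tree$parent != -1L))) # rev so file order pops first
    children[[pos[i]]] <- c(i, children[[pos[i]]])
  root <- which(tree$parent == -1L)

  pts <- matrix(NA_real_, 0, 3)
  pred <- integer(0)
  pred_arc <- numeric(0)
  edge_child <- integer(0)
  offset <- numeric(0)

  pts <- rbind(pts, c(tree$x[root], tree$y[root], tree$z[root]))
  pred <- c(pred, NA_integer_); pred_arc <- c(pred_arc, NA_real_)
  edge_child <- c(edge_child, root); offset <- c(offset, 0)

  # stack frames: node row, residual arclength, last sample index
  stack <- list(list(node = root, residual = 0, last = 1L))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    kids <- children[[fr$node]]
    for (k in rev(kids)) {
      p0 <- c(tree$x[fr$node], tree$y[fr$node], tree$z[fr$node])
      p1 <- c(tree$x[k], tree$y[k], tree$z[k])
      # identical expression to swc_sample_count so that the counting
      # pass and the emission pass agree bit for bit at boundary steps
      L <- sqrt((tree$x[k] - tree$x[fr$node])^2 +
                (tree$y[k] - tree$y[fr$node])^2 +
                (tree$z[k] - tree$z[fr$node])^2)
      resid <- fr$residual
      last <- fr$last
      m <- floor((resid + L) / step)
      if (m > 0) {
        for (j in seq_len(m)) {
          o <- j * step - resid
          pts <- rbind(pts, p0 + (o / L) * (p1 - p0))
          pred <- c(pred, last); pred_arc <- c(pred_arc, step)
          edge_child <- c(edge_child, k); offset <- c(offset, o)
          last <- nrow(pts)
        }
        resid <- resid + L - m * step
      } else {
        resid <- resid + L
      }
      stack[[length(stack) + 1L]] <- list(node = k, residual = resid, last = last)
    }
  }
  list(points = pts,
       provenance = data.frame(pred = pred, pred_arc = pred_arc,
                               edge_child = edge_child, offset = offset))
}

# Count the samples the walk above would emit for a given step,
# using the identical residual arithmetic (so that the binary search
# and the emission agree bit for bit even on boundary steps).
swc_sample_count <- function(tree, step) {
  pos <- match(tree$parent, tree$id)
  children <- vector("list", nrow(tree))
  for (i in rev(which(tree$parent != -1L)))
    children[[pos[i]]] <- c(i, children[[pos[i]]])
  root <- which(tree$parent == -1L)
  count <- 1L
  stack <- list(list(node = root, residual = 0))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (k in rev(children[[fr$node]])) {
      L <- sqrt((tree$x[k] - tree$x[fr$node])^2 +
                (tree$y[k] - tree$y[fr$node])^2 +
                (tree$z[k] - tree$z[fr$node])^2)
      m <- floor((fr$residual + L) / step)
      count <- count + m
      stack[[length(stack) + 1L]] <-
        list(node = k, residual = fr$residual + L - m * step)
    }
  }
  count
}

#' Evenly sample n points from a neuron skeleton
#'
#' Walks the tree from the soma accumulating arclength along every
#' root-to-leaf path and emits a point each time the distance from the
#' previously emitted point on that path reaches a fixed step, so the
#' samples grow radially (in geodesic radius) around the soma. The
#' step size yielding exactly `n` points is found by binary search
#' over \code{[total_length/(10 n), total_length]}; when several steps
#' give `n` points the largest is used. The soma is always the first
#' sample.
#'
#' @param tree a `neuron_tree`.
#' @param n number of points, at least 2.
#' @param max_iter binary-search iteration cap.
#' @return a `point_cloud` whose provenance records, per sample, the
#'   preceding sample on its path and the arclength between them.
#' @export
sample_swc_even <- function(tree, n, max_iter = 64L) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (n < 2)
    stop_morphgw("at least 2 sample points are required", "morphgw_value_error")
  total <- tree_total_length(tree)
  if (total <= 0)
    stop_morphgw("tree has no cable to sample (single node?)", "morphgw_value_error")

  lo <- total / (10 * n)   # count(lo) should be >= n
  hi <- total              # count(hi) = 1 < n
  if (swc_sample_count(tree, lo) < n) {
    # shrink until enough samples exist (very branch-heavy trees)
    while (swc_sample_count(tree, lo) < n && lo > total * 1e-12) lo <- lo / 2
    if (swc_sample_count(tree, lo) < n)
      stop_morphgw(sprintf("cannot place %d points on this tree", n),
                   "morphgw_sampling_error")
  }
  best <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cnt <- swc_sample_count(tree, mid)
    if (cnt == n) { best <- mid; lo <- mid }   # prefer the largest such step
    else if (cnt > n) lo <- mid
    else hi <- mid
  }
  if (is.na(best))
    stop_morphgw(
      sprintf("binary search did not find a step giving exactly %d points (last counts around %d)",
              n, swc_sample_count(tree, (lo + hi) / 2)),
      "morphgw_sampling_error"
    )
  w <- swc_walk_sample(tree, best)
  stopifnot(nrow(w$points) == n)
  new_point_cloud(w$points, cell_id = attr(tree, "cell_id") %||% "cell",
                  source = "swc_even", provenance = w$provenance, step = best)
}

#' Randomly sample n points from a neuron skeleton
#'
#' Points are drawn uniformly with respect to arclength measure over
#' the tree: an edge is selected with probability proportional to its
#' length and the position on it uniformly.
#'
#' @param tree a `neuron_tree`.
#' @param n number of points (>= 1).
#' @param seed RNG seed; identical calls are identical.
#' @return a `point_cloud` with edge/offset provenance.
#' @export
sample_swc_random <- function(tree, n, seed) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (n < 1) stop_morphgw("n must be positive", "morphgw_value_error")
  e <- tree_edge_lengths(tree)
  if (nrow(e) == 0)
    stop_morphgw("tree has no cable to sample (single node?)", "morphgw_value_error")
  with_seed(seed, {
    ei <- sample.int(nrow(e), n, replace = TRUE, prob = e[, "length"])
    o <- stats::runif(n) * e[ei, "length"]
    child <- e[ei, "child"]; parent <- e[ei, "parent"]
    t01 <- o / e[ei, "length"]
    pts <- cbind(tree$x[parent] + t01 * (tree$x[child] - tree$x[parent]),
                 tree$y[parent] + t01 * (tree$y[child] - tree$y[parent]),
                 tree$z[parent] + t01 * (tree$z[child] - tree$z[parent]))
    new_point_cloud(pts, cell_id = attr(tree, "cell_id") %||% "cell",
                    source = "swc_random",
                    provenance = data.frame(edge_child = child, offset = o))
  })
}

#' Evenly subsample mesh vertices
#'
#' Selects `n` vertex indices evenly spaced over the stored vertex
#' order (`round(k (V-1)/(n-1))` for `k = 0..n-1`, both endpoints
#' included). Mesh vertex order is roughly sorted by spatial
#' proximity in common segmentation outputs, so this approximates even
#' sampling over the surface.
#'
#' @param mesh a `tri_mesh` with at least `n` vertices.
#' @param n number of vertices to keep.
#' @return a `point_cloud` whose provenance holds the vertex indices.
#' @export
sample_mesh_vertices <- function(mesh, n) {
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- nrow(mesh$vertices)
  if (n < 2) stop_morphgw("at least 2 sample points are required", "morphgw_value_error")
  if (V < n)
    stop_morphgw(sprintf("mesh has %d vertices, fewer than n = %d", V, n),
                 "morphgw_too_few_vertices_error")
  idx <- if (n == 1) 1L else as.integer(round((seq_len(n) - 1) * (V - 1) / (n - 1))) + 1L
  new_point_cloud(mesh$vertices[idx, , drop = FALSE],
                  cell_id = attr(mesh, "cell_id") %||% "cell",
                  source = "mesh_vertices",
                  provenance = data.frame(vertex = idx))
}

#' Evenly sample n points from the outline of a segmentation mask
#'
#' Extracts the closed boundary contour of the (single) object by
#' Moore neighbour tracing, starting from the top-left boundary pixel
#' and proceeding clockwise, then emits `n` points at equal perimeter
#' arclength spacing starting at that pixel. Coordinates are scaled by
#' the mask's pixel size.
#'
#' @param mask a `seg_mask`.
#' @param n number of outline points.
#' @return a 2D `point_cloud`.
#' @export
sample_mask_outline <- function(mask, n) {
  stopifnot(inherits(mask, "seg_mask"))
  if (n < 2) stop_morphgw("at least 2 sample points are required", "morphgw_value_error")
  contour <- trace_moore_contour(mask$pixels)
  if (nrow(contour) < 2)
    stop_morphgw("object has a single pixel: no contour to sample",
                 "morphgw_no_contour_error")
  xy <- contour * mask$pixel_size
  seg <- sqrt(rowSums((xy - rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))^2))
  cum <- c(0, cumsum(seg))              # closed: last entry = perimeter
  per <- cum[length(cum)]
  want <- (seq_len(n) - 1) * per / n
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    j <- findInterval(want[i], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(xy))
    t0 <- if (seg[j] > 0) (want[i] - cum[j]) / seg[j] else 0
    nxt <- if (j == nrow(xy)) 1L else j + 1L
    pts[i, ] <- xy[j, ] + t0 * (xy[nxt, ] - xy[j, ])
  }
  new_point_cloud(pts, cell_id = "mask", source = "mask_outline",
                  provenance = data.frame(arclength = want))
}

# Moore neighbour tracing, clockwise, starting at the top-left
# (smallest row, then smallest column) foreground pixel. The scan at
# each step starts just after the background "backtrack" pixel, the
# classic formulation. Returns the contour as (x, y) = (col, row)
# pixel coordinates.
trace_moore_contour <- function(px) {
  fg <- which(px, arr.ind = TRUE)
  start <- fg[order(fg[, 1], fg[, 2])[1], ]
  # clockwise Moore neighbourhood in image coordinates (row grows down):
  # W, NW, N, NE, E, SE, S, SW
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  dir_index <- function(d) which(moves[, 1] == d[1] & moves[, 2] == d[2])
  is_fg <- function(p) p[1] >= 1 && p[1] <= nrow(px) &&
    p[2] >= 1 && p[2] <= ncol(px) && px[p[1], p[2]]

  cur <- start
  b <- start + c(0, -1)          # west of the top-left pixel: background
  b0 <- b
  contour <- matrix(c(start[2], start[1]), 1, 2)
  cap <- 8 * sum(px) + 8
  steps <- 0L
  repeat {
    i0 <- dir_index(b - cur)
    prev_bg <- b
    found <- FALSE
    for (s in 1:8) {
      k <- ((i0 - 1L + s) %% 8L) + 1L
      cand <- cur + moves[k, ]
      if (is_fg(cand)) {
        b <- prev_bg
        cur <- cand
        found <- TRUE
        break
      }
      prev_bg <- cand
    }
    if (!found) break   # isolated pixel: no contour
    steps <- steps + 1L
    if ((cur[1] == start[1] && cur[2] == start[2] &&
         b[1] == b0[1] && b[2] == b0[2]) || steps > cap) break
    contour <- rbind(contour, c(cur[2], cur[1]))
  }
  # drop a possible duplicate of the start appended before termination
  if (nrow(contour) > 1 &&
      all(contour[nrow(contour), ] == contour[1, ])) {
    contour <- contour[-nrow(contour), , drop = FALSE]
  }
  contour
}
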