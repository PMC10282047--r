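# Operations on the GW morphology space: medoid cells, alignment of
# cluster members to the medoid through their GW couplings, averaged
# distance matrices, the average-shape tree, Louvain clustering and
# 2D embedding.

#' Medoid cell of a subset of the morphology space
#'
#' The cell with the minimum sum of GW distances to all other cells in
#' the subset; ties are broken towards the smallest cell index.
#'
#' @param space a `gw_space`.
#' @param subset indices or cell ids (default: all cells).
#' @return the index (into `space$cell_ids`) of the medoid.
#' @export
medoid <- function(space, subset = NULL) {
  stopifnot(inherits(space, "gw_space"))
  idx <- resolve_subset(space, subset)
  if (length(idx) == 0)
    stop_morphgw("empty subset", "morphgw_value_error")
  sums <- rowSums(space$D[idx, idx, drop = FALSE])
  idx[which.min(sums)]   # which.min takes the first minimum: smallest index
}

resolve_subset <- function(space, subset) {
  if (is.null(subset)) return(seq_along(space$cell_ids))
  if (is.character(subset)) {
    idx <- match(subset, space$cell_ids)
    if (any(is.na(idx)))
      stop_morphgw("unknown cell id in subset", "morphgw_value_error")
    idx
  } else as.integer(subset)
}

#' Harden a GW coupling into a permutation
#'
#' Solves the maximum-weight bipartite assignment on the coupling
#' matrix (Hungarian algorithm), so the soft matching becomes a
#' consistent reindexing of one cell's points onto the other's.
#'
#' @param coupling n x n non-negative coupling matrix.
#' @return integer permutation: element `a` of the source is matched
#'   to `perm[a]` of the target.
#' @export
harden_coupling <- function(coupling) {
  if (nrow(coupling) != ncol(coupling))
    stop_morphgw("can only harden square couplings", "morphgw_shape_error")
  perm <- as.integer(clue::solve_LSAP(coupling, maximum = TRUE))
  w <- coupling[cbind(seq_len(nrow(coupling)), perm)]
  if (any(w <= 0))
    stop_morphgw("coupling too diffuse to harden: assignment uses zero-mass cells",
                 "morphgw_diffuse_coupling_error")
  perm
}

#' Align cluster members to the medoid
#'
#' Each cell's coupling to the medoid is hardened into a permutation
#' and its intracellular distance matrix conjugated by it, so that row
#' and column `g` of every aligned matrix refer to the same medoid
#' point `g`.
#'
#' @param matrices list of n x n `icdm` objects or matrices.
#' @param couplings list of n x n couplings of each cell to the medoid
#'   (rows = cell points, columns = medoid points).
#' @return list of aligned (reordered) matrices.
#' @export
align_to_medoid <- function(matrices, couplings) {
  if (length(matrices) != length(couplings))
    stop_morphgw("matrices and couplings differ in length", "morphgw_shape_error")
  lapply(seq_along(matrices), function(i) {
    D <- as_icdm_matrix(matrices[[i]])
    perm <- tryCatch(harden_coupling(couplings[[i]]),
                     morphgw_diffuse_coupling_error = function(e)
                       stop_morphgw(sprintf("cell %d: %s", i, conditionMessage(e)),
                                    "morphgw_diffuse_coupling_error"))
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    D[inv, inv, drop = FALSE]
  })
}

#' Averaged morphology distance matrix of a cluster
#'
#' Combines the medoid-aligned distance matrices of a cluster into a
#' single averaged matrix. In mode `"eq2"` this is the
#' coupling-weighted transport of every cell's distances onto the
#' medoid indexing, which for hardened (permutation) couplings equals
#' the entrywise mean of the aligned matrices, kept on the micrometre
#' scale. In mode `"thresholded"` each aligned matrix is first
#' rescaled to an unweighted graph distance: divided by its minimum
#' positive entry, rounded to integers, and clipped at 2 (0 = same
#' point, 1 = adjacent in the neuron trace, 2 = farther), then
#' averaged entrywise.
#'
#' @param aligned list of aligned n x n matrices from
#'   [align_to_medoid()].
#' @param mode `"eq2"` or `"thresholded"`.
#' @return the averaged matrix; in thresholded mode the per-cell
#'   clipped matrices are attached as `attr(, "per_cell")` and
#'   `attr(, "mode")` records the mode.
#' @export
average_morphology_matrix <- function(aligned, mode = c("eq2", "thresholded")) {
  mode <- match.arg(mode)
  if (length(aligned) == 0)
    stop_morphgw("empty cluster", "morphgw_value_error")
  n <- nrow(aligned[[1]])
  if (any(vapply(aligned, function(D) nrow(D) != n || ncol(D) != n, logical(1))))
    stop_morphgw("aligned matrices must share the same size", "morphgw_shape_error")
  if (mode == "eq2") {
    out <- Reduce(`+`, aligned) / length(aligned)
  } else {
    clipped <- lapply(aligned, function(D) {
      if (!any(D > 0))
        stop_morphgw("zero matrix: no positive minimum distance to rescale by",
                     "morphgw_value_error")
      pmin(round(D / min(D[D > 0])), 2)
    })
    out <- Reduce(`+`, clipped) / length(clipped)
    attr(out, "per_cell") <- clipped
  }
  attr(out, "mode") <- mode
  out
}

#' Average-shape tree of a cluster
#'
#' Builds the k = 3 nearest-neighbour graph of the averaged matrix
#' (connecting each sampled point to the three points it is most often
#' adjacent to across the cluster) and takes its shortest-path tree,
#' rooted at the soma sample (point 1), as the average shape. Each
#' point carries a confidence score: the clipped distance from the
#' point to its nearest neighbour, summed over the cells of the
#' cluster (lower = the point's local neighbourhood is more consistent
#' across cells); a copy normalized to [0, 1] is provided for display.
#'
#' @param d_hat averaged matrix from [average_morphology_matrix()].
#' @param k number of nearest neighbours (default 3).
#' @param root index of the root point (default 1, the soma sample).
#' @return list with `knn_graph` and `spt` (igraph objects),
#'   `confidence` (raw sums) and `confidence_scaled`.
#' @export
shape_tree <- function(d_hat, k = 3L, root = 1L) {
  n <- nrow(d_hat)
  mode <- attr(d_hat, "mode") %||% "eq2"
  # edge costs: for thresholded averages d_hat - 1 equals 1 minus the
  # fraction of cells in which the two points are adjacent
  costs <- if (mode == "thresholded") pmax(d_hat - 1, 0) else d_hat
  edges <- NULL
  wts <- NULL
  for (i in seq_len(n)) {
    ord <- order(d_hat[i, ], decreasing = FALSE)
    ord <- ord[ord != i][seq_len(min(k, n - 1))]
    edges <- rbind(edges, cbind(i, ord))
    wts <- c(wts, costs[cbind(i, ord)])
  }
  dup <- duplicated(t(apply(edges, 1, sort)))
  edges <- edges[!dup, , drop = FALSE]
  wts <- wts[!dup]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- wts

  comp <- igraph::components(g)
  if (comp$no > 1)
    warning(sprintf("kNN graph is disconnected (%d components); building a tree per component",
                    comp$no))
  spt_edges <- NULL
  for (cm in seq_len(comp$no)) {
    members <- which(comp$membership == cm)
    r <- if (root %in% members) root else members[1]
    paths <- igraph::shortest_paths(g, from = r, to = members,
                                    weights = igraph::E(g)$weight,
                                    output = "vpath")$vpath
    for (pth in paths) {
      pth <- as.integer(pth)
      if (length(pth) > 1)
        spt_edges <- rbind(spt_edges,
                           cbind(pth[-length(pth)], pth[-1]))
    }
  }
  spt_edges <- unique(spt_edges)
  spt <- igraph::graph_from_edgelist(spt_edges %||% matrix(integer(0), 0, 2),
                                     directed = FALSE)
  spt <- igraph::add_vertices(spt, max(0, n - igraph::vcount(spt)))

  per_cell <- attr(d_hat, "per_cell")
  confidence <- if (!is.null(per_cell)) {
    rowSums(vapply(per_cell, function(D) {
      apply(D + diag(Inf, n), 1, min)
    }, numeric(n)))
  } else {
    apply(d_hat + diag(Inf, n), 1, min) * 1
  }
  rng <- range(confidence)
  scaled <- if (diff(rng) > 0) (confidence - rng[1]) / diff(rng) else rep(0, n)
  list(knn_graph = g, spt = spt, confidence = confidence,
       confidence_scaled = scaled)
}

#' Average shape of a cluster, end to end
#'
#' Convenience pipeline: finds the medoid of the subset, computes GW
#' couplings of every member to it, aligns and averages the
#' intracellular matrices and builds the shape tree.
#'
#' @param space a `gw_space` over `cells`.
#' @param cells list of `icdm` objects in the order of
#'   `space$cell_ids`.
#' @param subset cluster member indices (default all).
#' @param mode averaging mode, see [average_morphology_matrix()].
#' @return list with `medoid`, `d_hat`, and the [shape_tree()] output.
#' @export
average_shape <- function(space, cells, subset = NULL,
                          mode = c("thresholded", "eq2")) {
  mode <- match.arg(mode)
  idx <- resolve_subset(space, subset)
  med <- medoid(space, idx)
  dmed <- cells[[med]]
  couplings <- lapply(idx, function(i) {
    if (i == med) diag(nrow(as_icdm_matrix(dmed))) / nrow(as_icdm_matrix(dmed))
    else gw_distance(cells[[i]], dmed)$coupling
  })
  aligned <- align_to_medoid(cells[idx], couplings)
  d_hat <- average_morphology_matrix(aligned, mode = mode)
  c(list(medoid = med, d_hat = d_hat), shape_tree(d_hat))
}

#' Louvain clustering of the morphology space
#'
#' Community detection on the unweighted k-nearest-neighbour graph of
#' the GW distance matrix.
#'
#' @param space a `gw_space`.
#' @param k_graph neighbours per cell in the kNN graph (edges are not
#'   required to be mutual).
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed (mandatory; Louvain refinement is stochastic).
#' @return a `cluster_labeling`: integer labels (1-based, contiguous)
#'   named by cell id, with the parameters in attributes.
#' @export
cluster_morphology <- function(space, k_graph = 15L, resolution = 1.0, seed) {
  stopifnot(inherits(space, "gw_space"))
  N <- length(space$cell_ids)
  if (N < k_graph + 1)
    stop_morphgw("need at least k_graph + 1 cells", "morphgw_value_error")
  g <- knn_graph_from_distances(space$D, k_graph)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  labels <- as.integer(factor(as.integer(memb)))
  names(labels) <- space$cell_ids
  structure(labels, class = "cluster_labeling",
            k_graph = k_graph, resolution = resolution, seed = seed)
}

knn_graph_from_distances <- function(D, k) {
  N <- nrow(D)
  edges <- NULL
  for (i in seq_len(N)) {
    ord <- order(D[i, ])
    ord <- ord[ord != i][seq_len(min(k, N - 1))]
    edges <- rbind(edges, cbind(i, ord))
  }
  dup <- duplicated(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges[!dup, , drop = FALSE], directed = FALSE)
  igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
}

#' 2D embedding of the morphology space
#'
#' UMAP on the precomputed GW distance matrix (neighbour graph built
#' from the distances directly). Seeded and single-threaded, so
#' repeated calls are identical.
#'
#' @param space a `gw_space`.
#' @param n_neighbors UMAP neighbourhood size; clamped to N - 1 with a
#'   warning on tiny spaces.
#' @param seed RNG seed.
#' @return N x 2 matrix of coordinates, rownames = cell ids.
#' @export
embed_2d <- function(space, n_neighbors = 15L, seed) {
  stopifnot(inherits(space, "gw_space"))
  N <- length(space$cell_ids)
  if (N < 3)
    stop_morphgw("need at least 3 cells to embed", "morphgw_value_error")
  if (N < n_neighbors + 1) {
    warning(sprintf("n_neighbors reduced from %d to %d for a %d-cell space",
                    n_neighbors, N - 1, N))
    n_neighbors <- N - 1
  }
  coords <- with_seed(seed, uwot::umap(
    stats::as.dist(space$D), n_neighbors = n_neighbors, n_components = 2,
    n_threads = 1, n_sgd_threads = 1, batch = FALSE
  ))
  rownames(coords) <- space$cell_ids
  coords
}
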