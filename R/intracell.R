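# Per-cell pairwise distance matrices over sampled points, under the
# Euclidean or geodesic metric. Geodesic distances are shortest paths
# on a graph: for neuron skeletons the chain of consecutively sampled
# points along the walk (each edge weighted by the arclength between
# the samples), for meshes the mesh edge graph weighted by edge
# length.

new_icdm <- function(D, cell_id, metric) {
  dimnames(D) <- NULL
  structure(list(cell_id = cell_id, metric = metric, D = D),
            class = "icdm")
}

#' @exportS3Method base::print
print.icdm <- function(x, ...) {
  cat(sprintf("<icdm> cell '%s': %d points, %s metric\n",
              x$cell_id, nrow(x$D), x$metric))
  invisible(x)
}

#' Euclidean intracellular distance matrix
#'
#' Pairwise straight-line distances between the sampled points of one
#' cell. Duplicate points are allowed (zero off-diagonal entries) and
#' reported with a warning.
#'
#' @param cloud a `point_cloud`.
#' @return an `icdm` with metric `"euclidean"`.
#' @export
euclidean_matrix <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$n < 2)
    stop_morphgw("need at least 2 points", "morphgw_value_error")
  D <- as.matrix(stats::dist(cloud$points))
  if (any(D[upper.tri(D)] == 0))
    warning("duplicate sampled points: zero off-diagonal distances present")
  new_icdm(D, cloud$cell_id, "euclidean")
}

#' Geodesic intracellular distance matrix for a neuron skeleton
#'
#' For an evenly sampled cloud, builds the weighted graph connecting
#' each sample to the previously emitted sample on its root-to-leaf
#' path (weight = arclength between them, i.e. the sampling step) and
#' returns all-pairs shortest path distances, computed by Dijkstra
#' from every sample. For a randomly sampled cloud the exact tree
#' metric is used instead, via the skeleton graph with sample points
#' inserted on their edges.
#'
#' @param tree the `neuron_tree` the cloud was sampled from.
#' @param cloud a `point_cloud` with SWC provenance.
#' @return an `icdm` with metric `"geodesic"`.
#' @export
geodesic_matrix_swc <- function(tree, cloud) {
  stopifnot(inherits(tree, "neuron_tree"), inherits(cloud, "point_cloud"))
  if (cloud$n < 2)
    stop_morphgw("need at least 2 points", "morphgw_value_error")
  prov <- cloud$provenance
  if (is.null(prov))
    stop_morphgw("cloud has no provenance; sample it from the tree first",
                 "morphgw_value_error")
  if (!is.null(prov$pred)) {
    e <- which(!is.na(prov$pred))
    g <- igraph::graph_from_edgelist(
      cbind(prov$pred[e], e), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, cloud$n - igraph::vcount(g)))
    igraph::E(g)$weight <- prov$pred_arc[e]
  } else {
    g <- swc_subdivided_graph(tree, prov)
  }
  comp <- igraph::components(g)
  if (comp$no > 1) {
    tab <- table(comp$membership[seq_len(cloud$n)])
    stop_morphgw(
      sprintf("sample graph is disconnected (%d components of sizes %s)",
              length(tab), paste(tab, collapse = ", ")),
      "morphgw_disconnected_error"
    )
  }
  D <- igraph::distances(g, v = seq_len(cloud$n), to = seq_len(cloud$n),
                         algorithm = "dijkstra")
  new_icdm(unname(D), cloud$cell_id, "geodesic")
}

# Graph over tree nodes plus sample points subdividing their edges;
# exact arclength metric on the skeleton.
swc_subdivided_graph <- function(tree, prov) {
  n_samp <- nrow(prov)
  n_node <- nrow(tree)
  pos <- match(tree$parent, tree$id)
  edges <- NULL
  wts <- NULL
  by_edge <- split(seq_len(n_samp), prov$edge_child)
  handled <- integer(0)
  for (child_str in names(by_edge)) {
    child <- as.integer(child_str)
    smp <- by_edge[[child_str]]
    ord <- smp[order(prov$offset[smp])]
    parent <- pos[child]
    if (is.na(parent)) {
      # samples sitting on the root itself (offset 0)
      for (s in ord) { edges <- rbind(edges, c(n_samp + child, s)); wts <- c(wts, 0) }
      next
    }
    L <- sqrt((tree$x[child] - tree$x[parent])^2 +
              (tree$y[child] - tree$y[parent])^2 +
              (tree$z[child] - tree$z[parent])^2)
    chain <- c(n_samp + parent, ord, n_samp + child)
    off <- c(0, prov$offset[ord], L)
    for (i in seq_len(length(chain) - 1)) {
      edges <- rbind(edges, c(chain[i], chain[i + 1]))
      wts <- c(wts, off[i + 1] - off[i])
    }
    handled <- c(handled, child)
  }
  rest <- setdiff(which(tree$parent != -1L), handled)
  for (child in rest) {
    parent <- pos[child]
    L <- sqrt((tree$x[child] - tree$x[parent])^2 +
              (tree$y[child] - tree$y[parent])^2 +
              (tree$z[child] - tree$z[parent])^2)
    edges <- rbind(edges, c(n_samp + parent, n_samp + child))
    wts <- c(wts, L)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_samp + n_node - igraph::vcount(g)))
  igraph::E(g)$weight <- wts
  g
}

#' Geodesic intracellular distance matrix on a mesh
#'
#' Shortest-path distances between the sampled vertices on the mesh
#' edge graph, each edge weighted by its Euclidean length. This is an
#' upper-bound approximation of the true surface geodesic; an exact or
#' heat-method backend can be substituted behind the same contract.
#'
#' @param mesh a `tri_mesh`.
#' @param cloud a `point_cloud` from [sample_mesh_vertices()].
#' @return an `icdm` with metric `"geodesic"`.
#' @export
geodesic_matrix_mesh <- function(mesh, cloud) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cloud, "point_cloud"))
  if (is.null(cloud$provenance$vertex))
    stop_morphgw("cloud lacks mesh vertex provenance", "morphgw_value_error")
  f <- mesh$faces
  if (nrow(f) == 0)
    stop_morphgw("mesh has no faces: no edge graph for geodesics",
                 "morphgw_value_error")
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  vid <- cloud$provenance$vertex
  memb <- igraph::components(g)$membership
  if (length(unique(memb[vid])) > 1)
    stop_morphgw("sampled vertices lie in different mesh components",
                 "morphgw_disconnected_error")
  D <- igraph::distances(g, v = vid, to = vid, algorithm = "dijkstra")
  new_icdm(unname(D), cloud$cell_id, "geodesic")
}

# metric-axioms check used by tests and validators
check_metric_axioms <- function(D, rel_tol = 1e-9) {
  s <- max(D)
  if (max(abs(D - t(D))) > rel_tol * max(1, s)) return("asymmetric")
  if (max(abs(diag(D))) > rel_tol * max(1, s)) return("nonzero diagonal")
  n <- nrow(D)
  for (k in seq_len(n)) {
    viol <- D - outer(D[, k], D[k, ], "+")
    if (max(viol) > rel_tol * max(1, s)) return("triangle inequality violated")
  }
  "ok"
}
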