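test_that("medoid minimizes the within-subset distance sum", {
  D <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3)
  sp <- gw_space(D, c("c1", "c2", "c3"))
  expect_equal(medoid(sp), 2L)                 # row sums 5, 3, 6
  expect_equal(medoid(sp, subset = 3L), 3L)    # singleton
  expect_error(medoid(sp, subset = integer(0)), class = "morphgw_value_error")
  # all-equal distances: first index wins
  spe <- gw_space(matrix(1, 4, 4) - diag(4))
  expect_equal(medoid(spe), 1L)
})

test_that("medoid is the brute-force argmin over random subsets", {
  set.seed(6)
  D <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  sp <- gw_space(D)
  for (r in 1:10) {
    sub <- sort(sample(8, sample(2:8, 1)))
    med <- medoid(sp, sub)
    sums <- sapply(sub, function(i) sum(D[i, sub]))
    expect_equal(med, sub[which.min(sums)])
  }
})

test_that("hardening couplings recovers the max-weight assignment", {
  # permutation-matrix coupling hardens to that permutation
  P <- matrix(0, 4, 4); P[cbind(1:4, c(3, 1, 4, 2))] <- 1 / 4
  expect_equal(harden_coupling(P), c(3L, 1L, 4L, 2L))
  # random soft couplings: compare against exhaustive search
  set.seed(12)
  for (r in 1:10) {
    T <- matrix(runif(16), 4, 4)
    perm <- harden_coupling(T)
    best <- -Inf; bestp <- NULL
    for (k in seq_len(nrow(all_perms(4)))) {
      pr <- all_perms(4)[k, ]
      w <- sum(T[cbind(1:4, pr)])
      if (w > best) { best <- w; bestp <- pr }
    }
    expect_equal(perm, as.integer(bestp))
  }
})

test_that("align_to_medoid conjugates matrices by the hardened permutation", {
  set.seed(8)
  D <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  # identity coupling: unchanged
  out <- align_to_medoid(list(D), list(diag(4) / 4))
  expect_equal(out[[1]], D)
  # permutation coupling: conjugation
  P <- matrix(0, 4, 4); P[cbind(1:4, c(2, 3, 4, 1))] <- 1 / 4
  out <- align_to_medoid(list(D), list(P))
  inv <- order(c(2, 3, 4, 1))
  expect_equal(out[[1]], D[inv, inv])
})

test_that("eq2 averaging with identity couplings is the arithmetic mean", {
  set.seed(14)
  mats <- lapply(1:5, function(i) as.matrix(dist(matrix(rnorm(12), 4, 3))))
  d_hat <- average_morphology_matrix(mats, mode = "eq2")
  expect_equal(unname(d_hat), Reduce(`+`, mats) / 5, ignore_attr = TRUE)
  # identical cells reduce to the common matrix
  same <- average_morphology_matrix(rep(mats[1], 4), mode = "eq2")
  expect_equal(unname(same), mats[[1]], ignore_attr = TRUE)
})

test_that("coupling-weighted transport matches a nested-loop evaluation", {
  # two cells, hand-set permutation couplings: the averaged matrix in
  # medoid indexing equals the direct two-sided transport sum with
  # cardinality normalization
  set.seed(15)
  D1 <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  D2 <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  p1 <- c(2L, 1L, 4L, 3L); p2 <- 1:4
  T1 <- matrix(0, 4, 4); T1[cbind(1:4, p1)] <- 1 / 4
  T2 <- diag(4) / 4
  aligned <- align_to_medoid(list(D1, D2), list(T1, T2))
  d_hat <- average_morphology_matrix(aligned, mode = "eq2")
  oracle <- matrix(0, 4, 4)
  for (Ti in list(list(T1, D1), list(T2, D2))) {
    Tm <- Ti[[1]]; Dm <- Ti[[2]]
    contrib <- matrix(0, 4, 4)
    for (a in 1:4) for (b in 1:4) for (g in 1:4) for (d in 1:4)
      contrib[a, b] <- contrib[a, b] + Tm[g, a] * Tm[d, b] * Dm[g, d]
    oracle <- oracle + 16 * contrib      # n^2 rescaling of the soft sum
  }
  oracle <- oracle / 2
  expect_equal(unname(d_hat), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("thresholded averaging rescales, rounds and clips at 2", {
  D <- matrix(c(0, 1, 2, 5,
                1, 0, 1, 2,
                2, 1, 0, 1,
                5, 2, 1, 0), 4) * 0.7   # scaled: min positive entry 0.7
  d_hat <- average_morphology_matrix(list(D), mode = "thresholded")
  expect_equal(sort(unique(as.vector(d_hat))), c(0, 1, 2))
  expect_equal(d_hat[1, 4], 2)  # 5 clipped to 2
  expect_equal(d_hat[1, 2], 1)
  zero <- matrix(0, 3, 3)
  expect_error(average_morphology_matrix(list(zero), mode = "thresholded"),
               class = "morphgw_value_error")
})

test_that("shape_tree of identical path cells is that path", {
  tr <- path_tree(seq(0, 10, by = 1))
  cl <- sample_swc_even(tr, 8)
  D <- geodesic_matrix_swc(tr, cl)$D
  d_hat <- average_morphology_matrix(rep(list(D), 6), mode = "thresholded")
  st <- shape_tree(d_hat)
  deg <- igraph::degree(st$spt)
  expect_equal(sum(deg == 1), 2)        # two endpoints
  expect_true(all(deg <= 2))            # no branching on a path
  expect_equal(igraph::ecount(st$spt), 7)
})

test_that("shape_tree of identical Y cells has exactly one branch point", {
  tr <- y_tree()
  cl <- sample_swc_even(tr, 20)
  D <- geodesic_matrix_swc(tr, cl)$D
  d_hat <- average_morphology_matrix(rep(list(D), 10), mode = "thresholded")
  st <- shape_tree(d_hat)
  expect_equal(igraph::ecount(st$spt), 19)            # spanning tree
  expect_equal(sum(igraph::degree(st$spt) >= 3), 1)   # single bifurcation
  expect_true(all(is.finite(st$confidence)))
  expect_true(all(st$confidence_scaled >= 0 & st$confidence_scaled <= 1))
})

test_that("shape_tree SPT edges match an independent recomputation", {
  set.seed(20)
  pts <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(dist(pts))
  d_hat <- average_morphology_matrix(list(D), mode = "eq2")
  st <- shape_tree(d_hat)
  # independent SPT: igraph's dijkstra on the same kNN graph from root 1
  g <- st$knn_graph
  sp <- igraph::shortest_paths(g, from = 1, to = igraph::V(g),
                               weights = igraph::E(g)$weight, output = "epath")
  edges_oracle <- sort(unique(unlist(lapply(sp$epath, function(e) as.integer(e)))))
  spt_el <- igraph::as_edgelist(st$spt)
  # compare as weighted edge sets via total weight of the tree
  w_spt <- sum(d_hat[spt_el])
  eo <- igraph::as_edgelist(g)[edges_oracle, , drop = FALSE]
  w_orc <- sum(d_hat[eo])
  expect_equal(w_spt, w_orc, tolerance = 1e-9)
})

test_that("clustering recovers planted blobs and is seed-stable", {
  set.seed(30)
  pts <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  sp <- gw_space(as.matrix(dist(pts)))
  lab <- cluster_morphology(sp, k_graph = 10, seed = 5)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand(lab, truth), 1)
  expect_identical(as.integer(lab),
                   as.integer(cluster_morphology(sp, k_graph = 10, seed = 5)))
  # tiny space still runs
  sp3 <- gw_space(as.matrix(dist(matrix(rnorm(6), 3, 2))))
  lab3 <- cluster_morphology(sp3, k_graph = 2, seed = 1)
  expect_equal(length(lab3), 3)
})

test_that("embedding is deterministic and separates planted blobs", {
  set.seed(33)
  pts <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 12), 30, 2))
  sp <- gw_space(as.matrix(dist(pts)))
  xy1 <- embed_2d(sp, n_neighbors = 10, seed = 4)
  xy2 <- embed_2d(sp, n_neighbors = 10, seed = 4)
  expect_identical(xy1, xy2)
  truth <- rep(1:2, each = 30)
  # silhouette of the embedding against the blob labels
  d <- as.matrix(dist(xy1))
  sil <- vapply(seq_len(60), function(i) {
    a <- mean(d[i, truth == truth[i] & seq_len(60) != i])
    b <- mean(d[i, truth != truth[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_warning(small <- embed_2d(gw_space(as.matrix(dist(matrix(rnorm(10), 5, 2)))),
                                   n_neighbors = 15, seed = 2),
                 "n_neighbors")
  expect_equal(nrow(small), 5)
})

test_that("average_shape pipeline reproduces a common cell exactly", {
  tr <- y_tree()
  cl <- sample_swc_even(tr, 15)
  d <- geodesic_matrix_swc(tr, cl)
  cells <- rep(list(d), 6)
  sp <- gw_pairwise(cells)
  av <- average_shape(sp, cells, mode = "eq2")
  expect_equal(unname(av$d_hat), d$D, ignore_attr = TRUE, tolerance = 1e-7)
})
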