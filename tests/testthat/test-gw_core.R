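test_that("two-point cells follow the closed-form GW value", {
  # interpoint spacings a and b give objective (a-b)^2/4, distance |a-b|/2
  set.seed(5)
  for (r in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    res <- gw_distance(matrix(c(0, a, a, 0), 2), matrix(c(0, b, b, 0), 2))
    expect_equal(res$objective, (a - b)^2 / 4, tolerance = 1e-10)
    expect_equal(res$distance, abs(a - b) / 2, tolerance = 1e-10)
  }
})

test_that("gw distance of a cell to itself is zero with a feasible coupling", {
  tr <- generate_neuron(neuron_spec(n_branches = 3), seed = 2)
  cl <- sample_swc_even(tr, 20)
  D <- euclidean_matrix(cl)
  res <- gw_distance(D, D)
  expect_equal(res$objective, 0, tolerance = 1e-12)
  expect_equal(unname(rowSums(res$coupling)), rep(1 / 20, 20), tolerance = 1e-9)
  expect_equal(unname(colSums(res$coupling)), rep(1 / 20, 20), tolerance = 1e-9)
})

test_that("rigid motions leave Euclidean GW at zero", {
  tr <- generate_neuron(neuron_spec(n_branches = 4), seed = 13)
  cl <- sample_swc_even(tr, 25)
  D1 <- euclidean_matrix(cl)$D
  D2 <- euclidean_matrix(rigid_transform(cl, seed = 77))$D
  expect_lt(gw_distance(D1, D2)$objective, 1e-10 * max(D1)^2)
})

test_that("gw evaluation is symmetric under argument order", {
  set.seed(9)
  for (r in 1:5) {
    A <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
    B <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
    f <- gw_distance(A, B)$objective
    g <- gw_distance(B, A)$objective
    expect_equal(f, g, tolerance = 1e-8)
  }
})

test_that("scaling one cell gives strictly positive distance", {
  A <- as.matrix(dist(matrix(rnorm(15), 5, 3)))
  expect_gt(gw_distance(A, 2 * A)$distance, 0.01 * max(A))
})

test_that("input validation rejects malformed problems", {
  A <- as.matrix(dist(matrix(rnorm(9), 3, 3)))
  expect_error(gw_distance(A[, 1:2], A), class = "morphgw_shape_error")
  expect_error(gw_distance(A, A, weights_a = c(0.5, 0.5, 0.5)),
               class = "morphgw_value_error")
  bad <- A; bad[1, 2] <- NaN
  expect_error(gw_distance(bad, A), class = "morphgw_value_error")
})

test_that("the coupling solves the stated marginal constraints", {
  set.seed(31)
  A <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  B <- as.matrix(dist(matrix(rnorm(18), 6, 3)))
  res <- gw_distance(A, B)
  expect_true(all(res$coupling >= -1e-12))
  expect_equal(unname(rowSums(res$coupling)), rep(1 / 4, 4), tolerance = 1e-9)
  expect_equal(unname(colSums(res$coupling)), rep(1 / 6, 6), tolerance = 1e-9)
  # objective equals the independent quadruple-loop evaluation
  expect_equal(res$objective, unname(gw_objective_loop(A, B, res$coupling)),
               tolerance = 1e-9)
})

test_that("the transportation LP oracle is optimal (dual certificate)", {
  set.seed(17)
  for (r in 1:10) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    cost <- matrix(runif(n * m), n, m)
    p <- runif(n); p <- p / sum(p)
    q <- runif(m); q <- q / sum(q)
    sol <- morphgw:::transport_simplex(cost, p, q)
    expect_equal(rowSums(sol$plan), p, tolerance = 1e-10)
    expect_equal(colSums(sol$plan), q, tolerance = 1e-10)
    expect_true(all(sol$plan >= -1e-12))
    # against uniform-case Hungarian on square instances
    if (n == m) {
      pu <- rep(1 / n, n)
      su <- morphgw:::transport_simplex(cost, pu, pu)
      perm <- clue::solve_LSAP(cost)
      expect_equal(su$cost, sum(cost[cbind(seq_len(n), as.integer(perm))]) / n,
                   tolerance = 1e-10)
    }
  }
})

test_that("gw_pairwise fills a symmetric space independent of worker count", {
  cells <- lapply(1:5, function(i) {
    tr <- generate_neuron(neuron_spec(n_branches = i %% 3), seed = i)
    d <- euclidean_matrix(sample_swc_even(tr, 15))
    d$cell_id <- sprintf("c%d", i)
    d
  })
  s1 <- gw_pairwise(cells, workers = 1)
  expect_s3_class(s1, "gw_space")
  expect_equal(unname(diag(s1$D)), rep(0, 5))
  s2 <- gw_pairwise(cells, workers = 2)
  expect_identical(s1$D, s2$D)
})

test_that("identical cells give an all-zero space", {
  tr <- generate_neuron(neuron_spec(n_branches = 2), seed = 4)
  d <- euclidean_matrix(sample_swc_even(tr, 12))
  sp <- gw_pairwise(list(d, d, d))
  expect_equal(max(sp$D), 0, tolerance = 1e-7)
})

test_that("three two-point cells reproduce the closed-form space", {
  cells <- lapply(c(1, 3, 5), function(a) matrix(c(0, a, a, 0), 2))
  sp <- gw_pairwise(cells)
  expect_equal(unname(sp$D),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3), tolerance = 1e-9)
})

test_that("entropic GW approaches the unregularized value as reg shrinks", {
  a <- 1; b <- 3
  dA <- matrix(c(0, a, a, 0), 2); dB <- matrix(c(0, b, b, 0), 2)
  vals <- vapply(c(1, 0.1, 0.01), function(e)
    gw_entropic(dA, dB, epsilon_reg = e)$objective, numeric(1))
  gaps <- abs(vals - 1.0)
  expect_true(all(diff(gaps) <= 1e-9))   # monotone approach
  expect_lt(gaps[3], 1e-6)
  expect_lt(gw_entropic(dA, dA, 0.01)$objective, 1e-8)
  expect_error(gw_entropic(dA, dB, 0), class = "morphgw_value_error")
})

test_that("triangle inequality holds for GW distances on fixture triples", {
  set.seed(101)
  cells <- lapply(1:6, function(i) as.matrix(dist(matrix(rnorm(18), 6, 3))))
  sp <- gw_pairwise(cells)
  D <- sp$D
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-4 * max(D))
})
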