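test_that("radius_graph thresholds at eps, with the median default", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1; D[1, 3] <- D[3, 1] <- 2; D[2, 3] <- D[3, 2] <- 3
  g <- radius_graph(D, eps = 1.5)
  expect_equal(sum(g$A) / 2, 1)
  expect_equal(g$A[1, 2], 1)
  gm <- radius_graph(D)                    # median of {1,2,3} = 2
  expect_equal(gm$eps, 2)
  expect_equal(sum(gm$A) / 2, 2)
  gc <- radius_graph(D, eps = 100)
  expect_equal(sum(gc$A) / 2, 3)
  expect_error(radius_graph(D, eps = -1), class = "morphgw_value_error")
})

test_that("laplacian_score matches hand computation and the loop oracle", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_equal(laplacian_score(c(0, 0, 1, 1), A), 0)
  expect_equal(laplacian_score(c(0, 1, 0, 1), A), 16)   # 4 / 0.25
  # affine invariance, exactly
  f <- c(0, 1, 0, 1)
  expect_identical(laplacian_score(2 * f + 3, A), laplacian_score(f, A))
  expect_error(laplacian_score(rep(1, 4), A), class = "morphgw_zero_variance_error")
})

test_that("laplacian_score equals the graph-Laplacian quadratic form", {
  set.seed(44)
  for (r in 1:100) {
    n <- sample(5:15, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    f <- rnorm(n)
    expect_equal(laplacian_score(f, A), laplacian_score_loop(f, A),
                 tolerance = 1e-12)
  }
})

test_that("permutation test is seed-reproducible and order invariant", {
  set.seed(50)
  pts <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30, 4), 15, 2))
  A <- radius_graph(as.matrix(dist(pts)))$A
  F <- cbind(loc = rep(0:1, each = 15) + rnorm(30, sd = 0.3),
             noise = rnorm(30))
  r1 <- permutation_test(F, A, n_perm = 200, seed = 9)
  r2 <- permutation_test(F, A, n_perm = 200, seed = 9)
  expect_identical(r1$p, r2$p)
  # column order does not change per-feature results
  r3 <- permutation_test(F[, 2:1], A, n_perm = 200, seed = 9)
  expect_equal(r3$p[r3$feature == "loc"], r1$p[r1$feature == "loc"])
  # consistent relabeling of cells leaves the observed scores unchanged
  # and the p-values equal up to permutation resampling noise
  perm <- sample(30)
  r4 <- permutation_test(F[perm, , drop = FALSE], A[perm, perm],
                         n_perm = 200, seed = 9)
  expect_equal(sort(r4$score), sort(r1$score), tolerance = 1e-12)
  expect_lt(max(abs(sort(r4$p) - sort(r1$p))), 0.08)
})

test_that("localized features score low and reach small p-values", {
  set.seed(51)
  pts <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 6), 30, 2))
  A <- radius_graph(as.matrix(dist(pts)))$A
  f_loc <- rep(0:1, each = 30)
  f_null <- rnorm(60)
  res <- permutation_test(cbind(loc = f_loc, null = f_null), A,
                          n_perm = 1000, seed = 3)
  expect_lte(res$p[res$feature == "loc"], 0.01)
  expect_gt(res$p[res$feature == "null"], 0.05)
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("zero-variance features are reported untested", {
  A <- matrix(0, 6, 6); A[1, 2] <- A[2, 1] <- 1
  F <- cbind(ok = rnorm(6), flat = rep(1, 6))
  expect_message(res <- permutation_test(F, A, n_perm = 100, seed = 1),
                 "untested")
  expect_true(is.na(res$p[res$feature == "flat"]))
  expect_false(is.na(res$p[res$feature == "ok"]))
})

test_that("covariate adjustment uses a shared permutation and OLS residuals", {
  set.seed(52)
  N <- 40
  age <- sample(1:5, N, replace = TRUE)
  # feature identical to the covariate must not be significant
  A <- radius_graph(as.matrix(dist(matrix(rnorm(N * 2), N, 2))))$A
  ps <- replicate(5, {
    f <- age + rnorm(N, sd = 0.1)
    res <- permutation_test(cbind(conf = f), A, covariates = cbind(age = age),
                            n_perm = 300, seed = sample.int(1e6, 1))
    res$p
  })
  expect_gt(median(ps), 0.2)
  expect_error(permutation_test(cbind(x = rnorm(N)), A,
                                covariates = cbind(flat = rep(2, N)),
                                n_perm = 100, seed = 1),
               class = "morphgw_zero_variance_error")
  expect_error(permutation_test(cbind(x = rnorm(N)), A, n_perm = 50, seed = 1),
               class = "morphgw_value_error")
})

test_that("prepare_expression normalizes and filters by detection band", {
  counts <- rbind(c(1, 5, 0, 10), c(4, 0, 0, 20))
  colnames(counts) <- c("g1", "g2", "g3", "g4")
  rownames(counts) <- c("cellA", "cellB")
  # cell totals 16 and 24
  out <- prepare_expression(counts, min_detect = 0, max_detect = 1.01)
  expect_equal(out[1, "g1"], log1p(5000 * 1 / 16))
  expect_equal(out[2, "g1"], log1p(5000 * 4 / 24))

  # detection filter: band [5%, 90%)
  n_cells <- 100
  cm <- cbind(
    rare = c(rep(1, 4), rep(0, 96)),       # 4% detected: dropped
    ubiq = c(rep(1, 95), rep(0, 5)),       # 95%: dropped
    ok = rep(c(1, 0), 50),                 # 50%: kept
    base = rep(1, 100)                     # keeps cell totals positive
  )
  out2 <- prepare_expression(cm)
  expect_false("rare" %in% colnames(out2))
  expect_false("ubiq" %in% colnames(out2))
  expect_true("ok" %in% colnames(out2))

  expect_error(prepare_expression(rbind(c(0, 0), c(1, 2))),
               class = "morphgw_value_error")
})

test_that("the two-point closed-form of normalization matches the stated rule", {
  counts <- rbind(c(1, 99), c(4, 196))    # totals 100 and 200
  out <- prepare_expression(counts, min_detect = 0, max_detect = 1.01)
  expect_equal(out[1, 1], log(1 + 50))
  expect_equal(out[2, 1], log(1 + 100))
})
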