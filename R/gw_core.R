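# Gromov-Wasserstein distances between intracellular distance
# matrices, and assembly of the pairwise GW matrix over a set of
# cells (the cell morphology space).
#
# The squared-loss GW objective between metric-measure spaces
# (dA, p) and (dB, q) over couplings T with marginals (p, q) is
#
#   GW(dA, dB) = 1/2 min_T sum_{a,b,c,d} (dA_ab - dB_cd)^2 T_ac T_bd.
#
# Expanding the square and using the fixed marginals,
#   f(T) = cA + cB - 2 <dA T dB, T>,   GW = f(T*) / 2,
# which is minimized by conditional gradient (Frank-Wolfe): the
# linearized subproblem is an exact optimal-transport LP, solved by
# the Hungarian algorithm for uniform equal-size marginals and by a
# transportation simplex otherwise; the line search is exact since
# the objective is quadratic along a segment.

# scale a positive matrix to the prescribed marginals (Sinkhorn)
sinkhorn_project <- function(K, p, q, iter = 200L) {
  u <- rep(1, length(p))
  v <- rep(1, length(q))
  for (s in seq_len(iter)) {
    v <- q / as.numeric(crossprod(K, u))
    u <- p / as.numeric(K %*% v)
  }
  u * K %*% diag(v, nrow = length(v))
}

gw_constants <- function(dA, dB, p, q) {
  cA <- sum(dA^2 * (p %o% p))
  cB <- sum(dB^2 * (q %o% q))
  cC <- matrix(as.numeric(dA^2 %*% p), length(p), length(q)) +
    matrix(as.numeric(dB^2 %*% q), length(p), length(q), byrow = TRUE)
  list(cA = cA, cB = cB, cC = cC)
}

gw_objective_f <- function(dA, dB, T, consts) {
  consts$cA + consts$cB - 2 * sum((dA %*% T %*% dB) * T)
}

# Exact linear-oracle for min <cost, S> over the transportation
# polytope U(p, q). Uniform equal-size marginals reduce to an
# assignment problem (Hungarian); the general case uses the
# transportation simplex below.
ot_linear_oracle <- function(cost, p, q) {
  n <- length(p); m <- length(q)
  if (n == m && max(abs(p - 1 / n)) < 1e-12 && max(abs(q - 1 / m)) < 1e-12) {
    perm <- clue::solve_LSAP(cost - min(cost) + 1)
    S <- matrix(0, n, m)
    S[cbind(seq_len(n), as.integer(perm))] <- 1 / n
    return(S)
  }
  transport_simplex(cost, p, q)$plan
}

# Transportation simplex (north-west-corner start + MODI pivoting).
# Exact LP solver for min <cost, T>, T >= 0, row sums p, col sums q.
transport_simplex <- function(cost, p, q, max_pivots = 100000L) {
  n <- length(p); m <- length(q)
  if (abs(sum(p) - sum(q)) > 1e-10)
    stop_morphgw("marginals have different total mass", "morphgw_value_error")
  # north-west corner initial basic feasible solution
  Tm <- matrix(0, n, m)
  basis <- matrix(FALSE, n, m)
  i <- 1L; j <- 1L
  rp <- p; cq <- q
  while (i <= n && j <= m) {
    x <- min(rp[i], cq[j])
    Tm[i, j] <- x
    basis[i, j] <- TRUE
    rp[i] <- rp[i] - x
    cq[j] <- cq[j] - x
    if (i == n && j == m) break
    if (rp[i] <= cq[j] && i < n) i <- i + 1L else j <- j + 1L
  }
  # ensure exactly n+m-1 basic cells (degenerate NW corner can miss some)
  while (sum(basis) < n + m - 1) {
    free <- which(!basis)
    added <- FALSE
    for (f in free) {
      basis[f] <- TRUE
      if (!basis_has_cycle(basis)) { added <- TRUE; break }
      basis[f] <- FALSE
    }
    if (!added) break
  }
  for (pivot in seq_len(max_pivots)) {
    uv <- modi_potentials(cost, basis)
    red <- cost - outer(uv$u, uv$v, "+")
    red[basis] <- 0
    ent <- which.min(red)
    if (red[ent] >= -1e-11 * max(1, max(abs(cost)))) break
    ei <- row(basis)[ent]; ej <- col(basis)[ent]
    cyc <- basis_cycle(basis, ei, ej)
    minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
    theta <- min(Tm[minus])
    sgn <- rep(c(1, -1), length.out = nrow(cyc))
    for (r in seq_len(nrow(cyc)))
      Tm[cyc[r, 1], cyc[r, 2]] <- Tm[cyc[r, 1], cyc[r, 2]] + sgn[r] * theta
    leave <- minus[which(abs(Tm[minus]) <= 1e-15)[1], , drop = FALSE]
    if (length(leave) == 0 || any(is.na(leave)))
      leave <- minus[1, , drop = FALSE]
    basis[leave[1, 1], leave[1, 2]] <- FALSE
    Tm[leave[1, 1], leave[1, 2]] <- 0
    basis[ei, ej] <- TRUE
  }
  list(plan = Tm, cost = sum(Tm * cost))
}

# Solve u_i + v_j = c_ij over the basis tree (u_1 = 0).
modi_potentials <- function(cost, basis) {
  n <- nrow(basis); m <- ncol(basis)
  u <- rep(NA_real_, n); v <- rep(NA_real_, m)
  u[1] <- 0
  repeat {
    progress <- FALSE
    idx <- which(basis, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (!is.na(u[i]) && is.na(v[j])) { v[j] <- cost[i, j] - u[i]; progress <- TRUE }
      else if (is.na(u[i]) && !is.na(v[j])) { u[i] <- cost[i, j] - v[j]; progress <- TRUE }
    }
    if (!progress) break
  }
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  list(u = u, v = v)
}

# TRUE if the bipartite graph of basic cells contains a cycle.
basis_has_cycle <- function(basis) {
  idx <- which(basis, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  g <- igraph::graph_from_edgelist(
    cbind(idx[, 1], nrow(basis) + idx[, 2]), directed = FALSE)
  igraph::ecount(g) > igraph::vcount(g) - igraph::components(g)$no
}

# Unique alternating cycle created by adding cell (ei, ej) to the
# basis tree; returned as cell coordinates starting at (ei, ej).
basis_cycle <- function(basis, ei, ej) {
  n <- nrow(basis)
  idx <- which(basis, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(idx[, 1], n + idx[, 2]), directed = FALSE)
  need <- max(c(idx[, 1], n + idx[, 2], ei, n + ej))
  g <- igraph::add_vertices(g, max(0, need - igraph::vcount(g)))
  path <- igraph::shortest_paths(g, from = ei, to = n + ej)$vpath[[1]]
  path <- as.integer(path)
  # path alternates row, col, row, col, ...; cells are consecutive pairs
  cells <- matrix(NA_integer_, 0, 2)
  for (s in seq_len(length(path) - 1)) {
    a <- path[s]; b <- path[s + 1]
    if (a <= n) cells <- rbind(cells, c(a, b - n)) else cells <- rbind(cells, c(b, a - n))
  }
  # close the cycle with the entering cell first
  rbind(c(ei, ej), cells[rev(seq_len(nrow(cells))), , drop = FALSE])
}

check_marginals <- function(w, n, what) {
  if (is.null(w)) return(rep(1 / n, n))
  if (length(w) != n)
    stop_morphgw(sprintf("%s weights have wrong length", what), "morphgw_shape_error")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
    stop_morphgw(sprintf("%s weights must be non-negative and sum to 1", what),
                 "morphgw_value_error")
  w
}

as_icdm_matrix <- function(x) {
  if (inherits(x, "icdm")) x$D else x
}

icdm_id <- function(x, default) {
  if (inherits(x, "icdm")) as.character(x$cell_id) else default
}

#' Gromov-Wasserstein distance between two cells
#'
#' Minimizes the squared-loss GW objective over couplings between the
#' two intracellular distance matrices by conditional gradient
#' (Frank-Wolfe) with an exact transportation LP as linear oracle and
#' exact line search. The objective is non-convex, so the solver runs
#' a small set of deterministic initializations -- the product
#' coupling, transport plans matching point eccentricities (the
#' first-lower-bound heuristic), and, on small instances, fixed
#' multiplicative perturbations of the product coupling -- and keeps
#' the best stationary point. The result is a feasible coupling and
#' the objective it attains (an upper bound on the true GW value);
#' no seed is involved, so repeated calls are identical.
#'
#' Evaluation is canonicalized (smaller matrix first, ties broken by
#' cell id) so `gw_distance(a, b)` and `gw_distance(b, a)` agree to
#' machine precision.
#'
#' @param dA,dB `icdm` objects or plain symmetric matrices.
#' @param weights_a,weights_b point weights (default uniform).
#' @param max_iter maximum conditional-gradient iterations per start.
#' @param tol relative objective-change convergence tolerance.
#' @param n_jitter_starts number of fixed perturbed initializations
#'   tried in addition to the structured ones; the default enables
#'   them only for instances of at most `jitter_max_n` points, where
#'   the objective landscape is roughest relative to their cost.
#' @param jitter_max_n size cutoff for the jittered starts.
#' @param search `"fast"` (the default; structured multi-start) or
#'   `"thorough"`: an additional global search that explores the
#'   coupling polytope with a large batch of mirror-descent runs from
#'   pseudo-random starts (drawn under a fixed internal seed, so still
#'   deterministic) and refines the best candidates by conditional
#'   gradient. Thorough search finds near-global optima reliably on
#'   cells of up to a few dozen points but its memory and time grow
#'   as the fourth power of the point count; it is intended for
#'   metric-quality analyses at reduced point counts.
#' @param n_search_starts batch size of the thorough search.
#' @return a `gw_result`: list with `objective` (the GW value,
#'   including the 1/2 factor, squared micrometres), `distance`
#'   (its square root), `coupling`, `converged`, `iterations`.
#' @export
gw_distance <- function(dA, dB, weights_a = NULL, weights_b = NULL,
                        max_iter = 1000L, tol = 1e-9,
                        n_jitter_starts = 8L, jitter_max_n = 8L,
                        search = c("fast", "thorough"),
                        n_search_starts = 2000L) {
  search <- match.arg(search)
  A <- as_icdm_matrix(dA); B <- as_icdm_matrix(dB)
  check_square_distance_matrix(A, "dA"); check_square_distance_matrix(B, "dB")
  idA <- icdm_id(dA, "A"); idB <- icdm_id(dB, "B")
  p <- check_marginals(weights_a, nrow(A), "source")
  q <- check_marginals(weights_b, nrow(B), "target")

  swap <- nrow(B) < nrow(A) || (nrow(B) == nrow(A) && idB < idA)
  if (swap) {
    res <- gw_solve_dispatch(B, A, q, p, max_iter, tol,
                             n_jitter_starts, jitter_max_n,
                             search, n_search_starts)
    res$coupling <- t(res$coupling)
    return(res)
  }
  gw_solve_dispatch(A, B, p, q, max_iter, tol, n_jitter_starts, jitter_max_n,
                    search, n_search_starts)
}

gw_solve_dispatch <- function(A, B, p, q, max_iter, tol, n_jitter, jitter_max_n,
                              search, n_search_starts) {
  best <- gw_solve_multistart(A, B, p, q, max_iter, tol, n_jitter, jitter_max_n)
  if (search == "thorough" && best$objective > 0) {
    thr <- gw_solve_thorough(A, B, p, q, max_iter, tol, n_search_starts)
    if (thr$objective < best$objective) best <- thr
  }
  best
}

# Global search: a batch of mirror-descent trajectories from
# pseudo-random feasible couplings (fixed internal seed; the caller's
# RNG state is untouched), followed by conditional-gradient refinement
# of the best candidates.
gw_solve_thorough <- function(A, B, p, q, max_iter, tol,
                              n_starts = 2000L, n_refine = 40L) {
  n <- length(p); m <- length(q)
  consts <- gw_constants(A, B, p, q)
  K <- kronecker(B, A)
  cCvec <- as.vector(consts$cC)
  fvec <- function(V) consts$cA + consts$cB - 2 * colSums(V * (K %*% V))
  ii <- rep(seq_len(n), m); jj <- rep(seq_len(m), each = n)
  Ei <- matrix(0, n, n * m); Ei[cbind(ii, seq_len(n * m))] <- 1
  Ej <- matrix(0, m, n * m); Ej[cbind(jj, seq_len(n * m))] <- 1
  sink_cols <- function(V, sweeps) {
    for (s in seq_len(sweeps)) {
      V <- V * (p / (Ei %*% V))[ii, , drop = FALSE]
      V <- V * (q / (Ej %*% V))[jj, , drop = FALSE]
    }
    V
  }
  V <- with_seed(20240601L,
                 matrix(stats::rexp(n * m * n_starts), n * m, n_starts))
  V <- sink_cols(V, 15)
  for (it in seq_len(40L)) {
    G <- cCvec - 4 * K %*% V
    eta <- (0.5 / max(abs(G))) * (1 - it / 60)
    V <- sink_cols(V * exp(-eta * G), 4)
  }
  top <- order(fvec(V))[seq_len(min(n_refine, n_starts))]
  best <- NULL
  for (k in top) {
    T0 <- sinkhorn_project(matrix(V[, k], n, m), p, q, 100)
    r <- gw_solve_fw(A, B, p, q, T0, max_iter, tol)
    if (is.null(best) || r$objective < best$objective) best <- r
  }
  best
}

# Deterministic initializations for the Frank-Wolfe solver.
gw_starts <- function(A, B, p, q, n_jitter, jitter_max_n) {
  n <- length(p); m <- length(q)
  eA <- as.numeric(A %*% p)          # mean distance to the cell's points
  eB <- as.numeric(B %*% q)
  starts <- list(p %o% q)
  starts[[2]] <- ot_linear_oracle(outer(eA, eB, function(x, y) (x - y)^2), p, q)
  if (n == m) {
    P <- matrix(0, n, m); P[cbind(order(eA), order(eB))] <- 1 / n
    starts[[length(starts) + 1L]] <- P
    P <- matrix(0, n, m); P[cbind(order(eA), rev(order(eB)))] <- 1 / n
    starts[[length(starts) + 1L]] <- P
  }
  if (max(n, m) <= jitter_max_n && n_jitter > 0) {
    for (amp in c(0.5, 1.5, 3)) for (k in seq_len(n_jitter)) {
      R <- outer(seq_len(n), seq_len(m), function(i, j) sin(k * i * 2.3 + j * 1.7))
      starts[[length(starts) + 1L]] <- sinkhorn_project((p %o% q) * exp(amp * R), p, q)
    }
    for (s in seq_len(160L)) {
      u <- vapply(seq_len(n * m), function(d)
        halton_digit(s + 20L, halton_primes[((d - 1L) %% 16L) + 1L]), numeric(1))
      starts[[length(starts) + 1L]] <-
        sinkhorn_project(matrix(-log(pmax(u, 1e-12)), n, m), p, q)
    }
  }
  starts
}

halton_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53)

halton_digit <- function(i, base) {
  f <- 1; r <- 0
  while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
  r
}

# Deterministic mirror-descent polish of a coupling: multiplicative
# gradient steps interleaved with Sinkhorn rescaling. Used to tighten
# the sublinear Frank-Wolfe tail at interior stationary points of
# small instances.
pg_polish <- function(A, B, p, q, T, iters = 2000L) {
  consts <- gw_constants(A, B, p, q)
  for (it in seq_len(iters)) {
    G <- consts$cC - 4 * A %*% T %*% B
    step <- (if (it <= iters / 2) 0.15 else 0.03) / max(abs(G))
    T <- T * exp(-step * G)
    T <- T * (p / rowSums(T))
    T <- sweep(T, 2, q / colSums(T), "*")
  }
  T <- sinkhorn_project(T, p, q, iter = 60)
  list(coupling = T, objective = max(0, gw_objective_f(A, B, T, consts) / 2))
}

gw_solve_multistart <- function(A, B, p, q, max_iter, tol, n_jitter, jitter_max_n) {
  best <- NULL
  for (T0 in gw_starts(A, B, p, q, n_jitter, jitter_max_n)) {
    res <- gw_solve_fw(A, B, p, q, T0, max_iter, tol)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (max(nrow(A), nrow(B)) <= jitter_max_n && best$objective > 0) {
    pol <- pg_polish(A, B, p, q, best$coupling)
    if (pol$objective < best$objective) {
      best$objective <- pol$objective
      best$distance <- sqrt(pol$objective)
      best$coupling <- pol$coupling
    }
  }
  best
}

gw_solve_fw <- function(A, B, p, q, T0, max_iter, tol) {
  consts <- gw_constants(A, B, p, q)
  T <- T0
  obj <- gw_objective_f(A, B, T, consts)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    M <- A %*% T %*% B
    grad <- consts$cC - 4 * M
    S <- ot_linear_oracle(grad, p, q)
    Delta <- S - T
    a <- -2 * sum((A %*% Delta %*% B) * Delta)
    b <- -4 * sum(M * Delta)
    gamma <- if (a > 0) min(1, max(0, -b / (2 * a))) else if (a + b < 0) 1 else 0
    if (gamma == 0) { converged <- TRUE; break }
    T <- T + gamma * Delta
    new_obj <- gw_objective_f(A, B, T, consts)
    if (abs(new_obj - obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj; converged <- TRUE; break
    }
    obj <- new_obj
  }
  objective <- max(0, unname(obj) / 2)
  dimnames(T) <- NULL
  structure(list(objective = objective, distance = sqrt(objective),
                 coupling = T, converged = converged, iterations = iters),
            class = "gw_result")
}

#' @exportS3Method base::print
print.gw_result <- function(x, ...) {
  cat(sprintf("<gw_result> distance %.6g (objective %.6g), %d iterations%s\n",
              x$distance, x$objective, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Pairwise GW matrix over a set of cells
#'
#' Computes [gw_distance()] for every unordered pair and assembles the
#' symmetric matrix of GW distances. Pairs are solved independently in
#' a canonical order, so the result does not depend on the number of
#' workers.
#'
#' @param cells list of `icdm` objects (or plain matrices).
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param store_couplings_to optional index of a reference cell; the
#'   couplings of every cell to it are retained in the result (used by
#'   the average-shape construction).
#' @param ... passed to [gw_distance()].
#' @return a `gw_space`; couplings, when requested, are in
#'   `attr(space, "couplings")`.
#' @export
gw_pairwise <- function(cells, workers = 1L, store_couplings_to = NULL, ...) {
  if (length(cells) < 2)
    stop_morphgw("need at least 2 cells", "morphgw_value_error")
  metrics <- unique(vapply(cells, function(x)
    if (inherits(x, "icdm")) x$metric else "unknown", character(1)))
  if (length(metrics) > 1)
    warning("mixing intracellular metrics across cells: ", paste(metrics, collapse = ", "))
  N <- length(cells)
  ids <- vapply(seq_len(N), function(i) icdm_id(cells[[i]], sprintf("cell_%d", i)),
                character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  run_one <- function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    tryCatch(list(ok = TRUE, value = gw_distance(cells[[i]], cells[[j]], ...)),
             error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  }
  res <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(pairs)), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(pairs)), run_one)
  }
  D <- matrix(0, N, N)
  failures <- character(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (res[[k]]$ok) {
      D[i, j] <- D[j, i] <- res[[k]]$value$distance
    } else {
      failures <- c(failures, sprintf("(%s, %s): %s", ids[i], ids[j], res[[k]]$value))
      D[i, j] <- D[j, i] <- NA_real_
    }
  }
  if (length(failures) > 0)
    stop(structure(
      class = c("morphgw_pairwise_error", "morphgw_error", "error", "condition"),
      list(message = sprintf("%d pairwise GW computations failed:\n%s",
                             length(failures), paste(failures, collapse = "\n")),
           call = sys.call(-1), partial = D, cell_ids = ids)
    ))
  space <- gw_space(D, ids)
  if (!is.null(store_couplings_to)) {
    ref <- store_couplings_to
    coup <- lapply(seq_len(N), function(i) {
      if (i == ref) {
        n <- nrow(as_icdm_matrix(cells[[i]]))
        diag(n) / n
      } else {
        gw_distance(cells[[i]], cells[[ref]], ...)$coupling
      }
    })
    attr(space, "couplings") <- coup
    attr(space, "reference") <- ref
  }
  space
}

#' Entropic-regularized GW distance
#'
#' Solves the entropy-regularized GW problem by mirror-descent
#' iterations: each step runs Sinkhorn scaling on the current
#' linearization of the objective. The reported objective is the
#' unregularized GW objective evaluated at the returned (feasible)
#' coupling; it approaches the [gw_distance()] value as
#' `epsilon_reg` decreases.
#'
#' @param dA,dB `icdm` objects or symmetric matrices.
#' @param epsilon_reg entropic regularization strength (> 0),
#'   squared micrometres.
#' @param seed seed for the small multiplicative jitter applied to the
#'   product-coupling initialization; the jitter lets the iteration
#'   escape the saddle the exact product coupling can form for highly
#'   symmetric inputs.
#' @param weights_a,weights_b marginals (default uniform).
#' @param max_outer,max_sinkhorn iteration caps.
#' @param tol stationarity tolerance on the coupling.
#' @return a `gw_result`.
#' @export
gw_entropic <- function(dA, dB, epsilon_reg, seed = 1L,
                        weights_a = NULL, weights_b = NULL,
                        max_outer = 200L, max_sinkhorn = 1000L, tol = 1e-9) {
  if (!is.numeric(epsilon_reg) || length(epsilon_reg) != 1 || epsilon_reg <= 0)
    stop_morphgw("epsilon_reg must be a positive number", "morphgw_value_error")
  A <- as_icdm_matrix(dA); B <- as_icdm_matrix(dB)
  check_square_distance_matrix(A, "dA"); check_square_distance_matrix(B, "dB")
  p <- check_marginals(weights_a, nrow(A), "source")
  q <- check_marginals(weights_b, nrow(B), "target")
  consts <- gw_constants(A, B, p, q)
  T <- (p %o% q) * with_seed(seed, matrix(exp(1e-3 * stats::rnorm(length(p) * length(q))),
                                          length(p), length(q)))
  T <- sinkhorn_project(T, p, q)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    iters <- it
    grad <- consts$cC - 4 * A %*% T %*% B
    K <- exp(-(grad - min(grad)) / epsilon_reg)
    if (any(rowSums(K) == 0) || any(colSums(K) == 0) || any(!is.finite(K)))
      stop_morphgw("numerical underflow in entropic scaling: increase epsilon_reg",
                   "morphgw_underflow_error")
    u <- rep(1, length(p))
    for (s in seq_len(max_sinkhorn)) {
      v <- q / as.numeric(crossprod(K, u))
      u_new <- p / as.numeric(K %*% v)
      if (max(abs(u_new - u)) < 1e-12 * max(1, max(abs(u_new)))) { u <- u_new; break }
      u <- u_new
    }
    T_new <- u * K %*% diag(v, nrow = length(v))
    if (any(!is.finite(T_new)))
      stop_morphgw("numerical underflow in entropic scaling: increase epsilon_reg",
                   "morphgw_underflow_error")
    if (max(abs(T_new - T)) < tol) { T <- T_new; converged <- TRUE; break }
    T <- T_new
  }
  objective <- max(0, gw_objective_f(A, B, T, consts) / 2)
  structure(list(objective = objective, distance = sqrt(objective),
                 coupling = T, converged = converged, iterations = iters),
            class = "gw_result")
}
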