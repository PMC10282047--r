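# Independent oracles used to cross-check the implementation:
# - quadruple-loop evaluation of the GW objective,
# - brute force over permutation couplings plus random feasible
#   couplings refined by projected (mirror-descent) gradient steps,
# - nested-loop Laplacian score.
# These deliberately avoid the package's solver code paths.

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  unname(out)
}

# direct quadruple-loop GW objective (including the 1/2 factor)
gw_objective_loop <- function(A, B, T) {
  s <- 0
  for (a in seq_len(nrow(A))) for (b in seq_len(nrow(A)))
    for (cc in seq_len(nrow(B))) for (d in seq_len(nrow(B)))
      s <- s + (A[a, b] - B[cc, d])^2 * T[a, cc] * T[b, d]
  s / 2
}

# brute-force GW: all permutation couplings (equal sizes) plus
# n_random random feasible couplings refined by projected gradient
oracle_gw <- function(A, B, n_random = 10000, seed = 1) {
  n <- nrow(A); m <- nrow(B)
  p <- rep(1 / n, n); q <- rep(1 / m, m)
  cA <- sum(A^2 * (p %o% p)); cB <- sum(B^2 * (q %o% q))
  K <- kronecker(B, A)
  cCvec <- as.vector(matrix(as.numeric(A^2 %*% p), n, m) +
                     matrix(as.numeric(B^2 %*% q), n, m, byrow = TRUE))
  fvec <- function(V) cA + cB - 2 * colSums(V * (K %*% V))
  best <- Inf
  if (n == m) {
    P <- all_perms(n)
    for (r in seq_len(nrow(P))) {
      T <- matrix(0, n, m)
      T[cbind(seq_len(n), P[r, ])] <- 1 / n
      best <- min(best, fvec(matrix(as.vector(T))))
    }
  }
  set.seed(seed)
  ii <- rep(seq_len(n), m); jj <- rep(seq_len(m), each = n)
  Ei <- matrix(0, n, n * m); Ei[cbind(ii, seq_len(n * m))] <- 1
  Ej <- matrix(0, m, n * m); Ej[cbind(jj, seq_len(n * m))] <- 1
  sink_proj <- function(V, sweeps) {
    for (s in seq_len(sweeps)) {
      V <- V * (p / (Ei %*% V))[ii, , drop = FALSE]
      V <- V * (q / (Ej %*% V))[jj, , drop = FALSE]
    }
    V
  }
  V <- sink_proj(matrix(stats::rexp(n * m * n_random), n * m, n_random), 20)
  for (it in 1:40) {
    G <- cCvec - 4 * K %*% V
    eta <- (0.5 / max(abs(G))) * (1 - it / 60)
    V <- V * exp(-eta * G)
    V <- sink_proj(V, 6)
  }
  top <- order(fvec(V))[seq_len(min(200, n_random))]
  W <- V[, top, drop = FALSE]
  for (it in 1:1500) {
    G <- cCvec - 4 * K %*% W
    W <- sink_proj(W * exp(-(0.15 / max(abs(G))) * G), 1)
  }
  for (it in 1:500) {
    G <- cCvec - 4 * K %*% W
    W <- sink_proj(W * exp(-(0.03 / max(abs(G))) * G), 1)
  }
  W <- sink_proj(W, 200)
  for (k in seq_len(ncol(W))) {
    T <- matrix(W[, k], n, m)
    # if the candidate sits near a vertex of the polytope, solve the
    # flows on its support exactly (peel leaves of the support forest)
    Th <- harden_support(T, p, q)
    if (!is.null(Th)) {
      best <- min(best, fvec(matrix(as.vector(Th))))
    }
    # exact rounding onto the polytope (rank-one deficit correction),
    # so the reported objective is attained by a feasible coupling
    T <- T * pmin(p / pmax(rowSums(T), 1e-300), 1)
    T <- sweep(T, 2, pmin(q / pmax(colSums(T), 1e-300), 1), "*")
    er <- p - rowSums(T); ec <- q - colSums(T)
    if (sum(er) > 0) T <- T + (er %o% ec) / sum(er)
    W[, k] <- as.vector(T)
  }
  min(best, min(fvec(W))) / 2
}

# Exact basic feasible solution on the support of T (entries above a
# relative threshold); NULL if the support is cyclic or infeasible.
harden_support <- function(T, p, q, thresh = 1e-4) {
  n <- length(p); m <- length(q)
  S <- T > thresh * max(T)
  out <- matrix(0, n, m)
  rp <- p; cq <- q
  repeat {
    if (!any(S)) break
    rdeg <- rowSums(S); cdeg <- colSums(S)
    i <- which(rdeg == 1)
    j <- which(cdeg == 1)
    if (length(i) > 0) {
      i <- i[1]; jj <- which(S[i, ])[1]
      out[i, jj] <- rp[i]
      cq[jj] <- cq[jj] - rp[i]; rp[i] <- 0
      S[i, jj] <- FALSE
    } else if (length(j) > 0) {
      j <- j[1]; ii <- which(S[, j])[1]
      out[ii, j] <- cq[j]
      rp[ii] <- rp[ii] - cq[j]; cq[j] <- 0
      S[ii, j] <- FALSE
    } else {
      return(NULL)   # cyclic support: not a vertex
    }
  }
  if (any(out < -1e-12) || max(abs(rp)) > 1e-9 || max(abs(cq)) > 1e-9)
    return(NULL)
  pmax(out, 0)
}

# nested-loop Laplacian score over ordered pairs
laplacian_score_loop <- function(f, A) {
  s <- 0
  n <- length(f)
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + (f[i] - f[j])^2 * A[i, j]
  s / mean((f - mean(f))^2)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
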