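# Laplacian-score feature association on the morphology space:
# radius neighbour graph, score, covariate-adjusted permutation test
# with Benjamini-Hochberg correction, and expression preprocessing.

#' Radius neighbour graph of the GW distance
#'
#' Binary adjacency connecting every pair of cells at GW distance at
#' most `eps`. With `eps = "median"` (the default) the radius is the
#' median of the off-diagonal GW distances.
#'
#' @param space a `gw_space` or symmetric distance matrix.
#' @param eps positive radius in micrometres, or `"median"`.
#' @return a `neighbor_graph`: list with binary symmetric `A`, `eps`,
#'   and the number of isolated cells.
#' @export
radius_graph <- function(space, eps = "median") {
  D <- if (inherits(space, "gw_space")) space$D else space
  check_square_distance_matrix(D, "distance matrix")
  if (identical(eps, "median")) {
    eps <- stats::median(condense_matrix(D))
  } else if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    stop_morphgw("eps must be a positive number or \"median\"", "morphgw_value_error")
  }
  A <- (D <= eps) * 1
  diag(A) <- 0
  isolated <- sum(rowSums(A) == 0)
  if (isolated > 0)
    message(sprintf("%d isolated cell(s) in the radius graph", isolated))
  structure(list(A = A, eps = eps, n_isolated = isolated),
            class = "neighbor_graph")
}

#' @exportS3Method base::print
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, eps = %.4g, %d edges, %d isolated\n",
              nrow(x$A), x$eps, sum(x$A) / 2, x$n_isolated))
  invisible(x)
}

as_adjacency <- function(A) {
  if (inherits(A, "neighbor_graph")) A$A else A
}

var_pop <- function(f) mean((f - mean(f))^2)

#' Laplacian score of a feature on the morphology space
#'
#' \deqn{C = \sum_{ij} (f_i - f_j)^2 A_{ij} / Var(f)} with the sum
#' over ordered pairs and the population variance (divisor N). Low
#' scores indicate features that vary little between morphologically
#' neighbouring cells (localized features). The score is invariant
#' under affine transformations of the feature.
#'
#' @param f numeric feature vector, one value per cell.
#' @param A a `neighbor_graph` or binary adjacency matrix.
#' @return the score, a non-negative scalar.
#' @export
laplacian_score <- function(f, A) {
  A <- as_adjacency(A)
  if (length(f) != nrow(A))
    stop_morphgw("feature length does not match graph size", "morphgw_shape_error")
  v <- var_pop(f)
  if (v == 0)
    stop_morphgw("zero-variance feature: score undefined", "morphgw_zero_variance_error")
  L <- diag(rowSums(A)) - A
  2 * as.numeric(crossprod(f, L %*% f)) / v
}

#' Covariate-adjusted permutation test of Laplacian scores
#'
#' For every feature, the null distribution of the score is obtained
#' by jointly permuting the feature and all covariates with a single
#' shared permutation per replicate. With covariates, the null scores
#' of the feature are regressed (ordinary least squares with
#' intercept) on the null scores of the covariates; the residuals form
#' the null distribution of the adjusted score
#' \eqn{\tilde C_g = C_g - \beta_0 - \sum_m \beta_m C_{h_m}}. The
#' one-tailed p-value (low scores significant) is
#' `(1 + #\{null <= observed\}) / (n_perm + 1)`, and q-values are
#' Benjamini-Hochberg adjusted across the tested features.
#' Zero-variance features are reported untested (NA).
#'
#' @param features numeric matrix or data frame, cells x features.
#' @param A a `neighbor_graph` or adjacency matrix.
#' @param covariates optional numeric matrix/data frame of covariates
#'   (cells x covariates), e.g. age.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return an `association_result` data frame with columns `feature`,
#'   `score`, `adj_score`, `p`, `q`; regression coefficients, observed
#'   covariate scores, seed and `n_perm` are stored in attributes.
#' @export
permutation_test <- function(features, A, covariates = NULL,
                             n_perm = 1000L, seed = 1L) {
  A <- as_adjacency(A)
  F <- as.matrix(features)
  if (is.null(colnames(F))) colnames(F) <- sprintf("feature_%d", seq_len(ncol(F)))
  N <- nrow(A)
  if (nrow(F) != N)
    stop_morphgw("feature rows do not match graph size", "morphgw_shape_error")
  if (n_perm < 100)
    stop_morphgw("n_perm must be at least 100", "morphgw_value_error")
  H <- NULL
  if (!is.null(covariates)) {
    H <- as.matrix(covariates)
    if (nrow(H) != N)
      stop_morphgw("covariate rows do not match graph size", "morphgw_shape_error")
    hv <- apply(H, 2, var_pop)
    if (any(hv == 0))
      stop_morphgw("zero-variance covariate", "morphgw_zero_variance_error")
  }
  L <- diag(rowSums(A)) - A
  score_cols <- function(M) {
    v <- apply(M, 2, var_pop)
    num <- 2 * colSums(M * (L %*% M))
    ifelse(v > 0, num / v, NA_real_)
  }
  obs <- score_cols(F)
  tested <- which(!is.na(obs))
  if (length(tested) < ncol(F))
    message(sprintf("%d zero-variance feature(s) reported untested",
                    ncol(F) - length(tested)))
  obs_h <- if (!is.null(H)) score_cols(H) else NULL

  perms <- with_seed(seed, replicate(n_perm, sample.int(N), simplify = FALSE))
  null_f <- matrix(NA_real_, n_perm, ncol(F))
  null_h <- if (!is.null(H)) matrix(NA_real_, n_perm, ncol(H)) else NULL
  for (r in seq_len(n_perm)) {
    idx <- perms[[r]]
    null_f[r, ] <- score_cols(F[idx, , drop = FALSE])
    if (!is.null(H)) null_h[r, ] <- score_cols(H[idx, , drop = FALSE])
  }

  p <- adj <- rep(NA_real_, ncol(F))
  betas <- vector("list", ncol(F))
  for (gi in tested) {
    if (is.null(H)) {
      p[gi] <- (1 + sum(null_f[, gi] <= obs[gi])) / (n_perm + 1)
      adj[gi] <- obs[gi]
    } else {
      fit <- stats::lm.fit(cbind(1, null_h), null_f[, gi])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      betas[[gi]] <- beta
      adj[gi] <- obs[gi] - beta[1] - sum(beta[-1] * obs_h)
      p[gi] <- (1 + sum(fit$residuals <= adj[gi])) / (n_perm + 1)
    }
  }
  q <- rep(NA_real_, ncol(F))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(feature = colnames(F), score = obs, adj_score = adj,
                    p = p, q = q, row.names = NULL)
  attr(out, "beta") <- betas
  attr(out, "covariate_scores") <- obs_h
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("association_result", "data.frame")
  out
}

#' Prepare a gene-expression feature table
#'
#' Size-normalizes counts per cell (divides by the cell's total),
#' multiplies by 5000 and applies `log(1 + x)`. Genes detected in
#' fewer than 5% or in at least 90% of cells are dropped.
#'
#' @param counts non-negative count matrix, cells x genes.
#' @param min_detect,max_detect detection-fraction band; genes with
#'   detection fraction in `[min_detect, max_detect)` are kept.
#' @param scale size-normalization scale factor.
#' @return the normalized cells x genes matrix of kept genes; the
#'   kept/dropped report is in `attr(, "filter")`.
#' @export
prepare_expression <- function(counts, min_detect = 0.05, max_detect = 0.90,
                               scale = 5000) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    stop_morphgw("negative counts", "morphgw_value_error")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop_morphgw("cell with zero total count", "morphgw_value_error")
  detect <- colMeans(counts > 0)
  keep <- detect >= min_detect & detect < max_detect
  norm <- log1p(scale * counts[, keep, drop = FALSE] / totals)
  attr(norm, "filter") <- data.frame(
    gene = colnames(counts) %||% sprintf("gene_%d", seq_len(ncol(counts))),
    detection = detect, kept = keep, row.names = NULL)
  norm
}
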