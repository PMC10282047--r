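# Benchmarking statistics for morphology spaces: median-based
# group-discrimination score, cross-validated kNN classification
# (accuracy and multiclass Matthews correlation), and the
# modality-discrepancy 2-simplex coordinates.

#' Median-based group discrimination score
#'
#' For every label, the ratio of the median between-group distance
#' (members vs non-members) to the median within-group distance
#' (pairs of members); the score is the mean of the per-label ratios.
#' Values near 1 indicate no separation. This median-ratio reading of
#' the classic cell-type separation statistic is a declared stand-in
#' for the original formulation.
#'
#' @param space a `gw_space` or distance matrix.
#' @param labels per-cell categorical labels.
#' @return list with `cts` (the mean ratio) and `per_label`.
#' @export
cts_score <- function(space, labels) {
  D <- if (inherits(space, "gw_space")) space$D else space
  labels <- as.character(labels)
  if (length(labels) != nrow(D))
    stop_morphgw("labels do not match matrix size", "morphgw_shape_error")
  tab <- table(labels)
  if (length(tab) < 2)
    stop_morphgw("need at least 2 labels", "morphgw_value_error")
  if (any(tab < 2))
    stop_morphgw(sprintf("label '%s' has fewer than 2 members",
                         names(tab)[which(tab < 2)[1]]),
                 "morphgw_value_error")
  per <- vapply(names(tab), function(l) {
    inl <- labels == l
    within <- D[inl, inl][upper.tri(D[inl, inl])]
    between <- as.numeric(D[inl, !inl])
    stats::median(between) / stats::median(within)
  }, numeric(1))
  list(cts = mean(per), per_label = per)
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's generalization of the MCC to a K x K confusion matrix
#' (rows = true, columns = predicted); equals the familiar binary MCC
#' for K = 2 and the Pearson correlation of one-hot encodings.
#'
#' @param confusion square non-negative matrix of counts.
#' @return value in [-1, 1].
#' @export
mcc <- function(confusion) {
  C <- as.matrix(confusion)
  if (nrow(C) != ncol(C) || any(C < 0))
    stop_morphgw("confusion matrix must be square and non-negative",
                 "morphgw_value_error")
  s <- sum(C)
  if (s == 0)
    stop_morphgw("all-zero confusion matrix", "morphgw_value_error")
  c_ <- sum(diag(C))
  t_ <- rowSums(C)   # true class totals
  p_ <- colSums(C)   # predicted class totals
  num <- c_ * s - sum(p_ * t_)
  den <- sqrt(s^2 - sum(p_^2)) * sqrt(s^2 - sum(t_^2))
  if (den == 0) return(0)
  num / den
}

#' Cross-validated kNN classification of labels from the space
#'
#' Repeated stratified f-fold cross-validation of a k-nearest
#' neighbour classifier operating directly on the precomputed
#' distance matrix: each held-out cell is assigned the majority label
#' among its k nearest training cells; ties are broken by the
#' smallest summed distance among the tied classes, then by label
#' order. Repeats differ only in the fold-assignment seed.
#'
#' @param space a `gw_space` or distance matrix.
#' @param labels per-cell categorical labels.
#' @param k neighbours used for the vote.
#' @param folds number of folds.
#' @param n_repeats number of random fold assignments.
#' @param seed RNG seed.
#' @return list with mean `accuracy`, mean `mcc` and a `per_repeat`
#'   data frame.
#' @export
knn_cv_classify <- function(space, labels, k = 10L, folds = 7L,
                            n_repeats = 10L, seed = 1L) {
  D <- if (inherits(space, "gw_space")) space$D else space
  labels <- factor(labels)
  N <- nrow(D)
  if (length(labels) != N)
    stop_morphgw("labels do not match matrix size", "morphgw_shape_error")
  if (N < folds)
    stop_morphgw("fewer cells than folds", "morphgw_value_error")
  acc <- mccs <- numeric(n_repeats)
  lev <- levels(labels)
  for (r in seq_len(n_repeats)) {
    fold_of <- with_seed(seed + r - 1L, stratified_folds(labels, folds))
    pred <- character(N)
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      if (length(unique(labels[train])) < length(lev))
        stop_morphgw(
          sprintf("stratification failure: class absent from training fold %d", f),
          "morphgw_stratification_error")
      if (k >= length(train))
        stop_morphgw("k must be smaller than the training-fold size",
                     "morphgw_value_error")
      for (i in test) {
        d <- D[i, train]
        nn <- train[order(d)[seq_len(k)]]
        votes <- table(labels[nn])
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1) {
          sums <- vapply(top, function(cl)
            sum(D[i, nn[labels[nn] == cl]]), numeric(1))
          top <- top[order(sums, match(top, lev))]
        }
        pred[i] <- top[1]
      }
    }
    pred <- factor(pred, levels = lev)
    acc[r] <- mean(pred == labels)
    mccs[r] <- mcc(table(labels, pred))
  }
  list(accuracy = mean(acc), mcc = mean(mccs),
       per_repeat = data.frame(repeat_ = seq_len(n_repeats),
                               accuracy = acc, mcc = mccs))
}

# assign members of each class to folds round-robin after a shuffle
stratified_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  for (l in levels(labels)) {
    members <- which(labels == l)
    members <- members[sample.int(length(members))]
    fold_of[members] <- rep(seq_len(folds), length.out = length(members))
  }
  fold_of
}

#' Modality-discrepancy simplex coordinates
#'
#' Compares morphological, transcriptomic and electrophysiological
#' pairwise distances over the same cells. The logarithm of the
#' off-diagonal distances is z-standardized independently per
#' modality, and each cell pair is placed on a 2-simplex with axes
#' `dM - dT`, `dT - dE`, `dE - dM`, which sum to zero exactly. Pairs
#' with a non-positive distance in any modality (log undefined) are
#' skipped and counted. The `trimmed` column flags pairs outside the
#' middle 98% of any axis (for plotting exports).
#'
#' @param dM,dT,dE distance matrices over the same cells
#'   (morphological, transcriptomic, electrophysiological).
#' @return data frame with pair indices, the three coordinates and
#'   `trimmed`; the number of skipped pairs is in
#'   `attr(, "n_skipped")`.
#' @export
modality_simplex <- function(dM, dT, dE) {
  dM <- if (inherits(dM, "gw_space")) dM$D else dM
  dims <- vapply(list(dM, dT, dE), nrow, numeric(1))
  if (length(unique(dims)) != 1 || any(dims != ncol(dM)))
    stop_morphgw("the three matrices must be square over the same cells",
                 "morphgw_shape_error")
  idx <- which(upper.tri(dM), arr.ind = TRUE)
  v <- cbind(dM[upper.tri(dM)], dT[upper.tri(dT)], dE[upper.tri(dE)])
  ok <- rowSums(v <= 0) == 0
  n_skipped <- sum(!ok)
  z <- scale(log(v[ok, , drop = FALSE]))
  out <- data.frame(
    i = idx[ok, 1], j = idx[ok, 2],
    m_minus_t = z[, 1] - z[, 2],
    t_minus_e = z[, 2] - z[, 3],
    e_minus_m = z[, 3] - z[, 1]
  )
  lim <- function(x) stats::quantile(x, c(0.01, 0.99))
  lm_ <- lim(out$m_minus_t); lt_ <- lim(out$t_minus_e); le_ <- lim(out$e_minus_m)
  out$trimmed <- out$m_minus_t < lm_[1] | out$m_minus_t > lm_[2] |
    out$t_minus_e < lt_[1] | out$t_minus_e > lt_[2] |
    out$e_minus_m < le_[1] | out$e_minus_m > le_[2]
  attr(out, "n_skipped") <- n_skipped
  out
}
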