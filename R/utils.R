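# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_morphgw <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "morphgw_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Condensed upper-triangle (row-major) <-> square symmetric matrix.
condense_matrix <- function(D) {
  D[upper.tri(D)][order(row(D)[upper.tri(D)], col(D)[upper.tri(D)])]
}

# row-major upper triangle packing: entry (i,j), i<j, at position
# (i-1)*N - i*(i-1)/2 + (j-i)
uncondense_matrix <- function(v, n) {
  D <- matrix(0, n, n)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  D[idx] <- v
  D[idx[, c(2, 1), drop = FALSE]] <- v
  D
}

is_symmetric_zero_diag <- function(D, tol = 1e-8) {
  is.matrix(D) && nrow(D) == ncol(D) &&
    max(abs(D - t(D))) <= tol * max(1, max(abs(D))) &&
    all(abs(diag(D)) <= tol * max(1, max(abs(D))))
}

check_square_distance_matrix <- function(D, what = "distance matrix") {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_morphgw(sprintf("%s must be a square matrix", what), "morphgw_shape_error")
  if (any(!is.finite(D)))
    stop_morphgw(sprintf("%s contains non-finite values", what), "morphgw_value_error")
  invisible(D)
}
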