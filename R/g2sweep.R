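#' g2 generalized inverse of a covariance matrix by sweeping
#'
#' Applies the sweep operator once to each column of a symmetric positive
#' semidefinite matrix in succession (Goodnight's G2SWEEP algorithm).  A
#' column whose pivot falls below `tol` times the largest original diagonal
#' element is declared linearly dependent on the previously swept columns and
#' has its row and column zeroed.  The result `G` is a reflexive (g2)
#' generalized inverse: `A G A = A` and `G A G = G`; for full-rank `A` it is
#' the ordinary inverse.  The number of swept columns is the rank, i.e. the
#' dimension of a full-rank subset.
#'
#' @param A symmetric positive semidefinite matrix.
#' @param tol relative pivot tolerance.
#' @return list with `G`, `rank`, and `dependent` (indices of zeroed
#'   columns).
#' @export
g2_sweep_inverse <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A) || !isSymmetric(unname(A), tol = 1e-8))
    stop("A must be symmetric")
  scale <- max(diag(A), 0)
  if (scale == 0) {
    return(list(G = matrix(0, n, n), rank = 0L, dependent = seq_len(n)))
  }
  W <- unname(A)
  dependent <- integer(0)
  for (k in seq_len(n)) {
    d <- W[k, k]
    if (d < tol * scale) {
      W[k, ] <- 0
      W[, k] <- 0
      dependent <- c(dependent, k)
      next
    }
    col_k <- W[, k]
    W <- W - tcrossprod(col_k) / d
    W[k, ] <- col_k / d
    W[, k] <- col_k / d
    W[k, k] <- -1 / d
  }
  # after sweeping every independent column the result is -A^-g2
  list(G = -W, rank = n - length(dependent), dependent = dependent)
}
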