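#' Weighted Sum Statistic (WSS) rank-sum test, modified
#'
#' The original weighted-sum procedure with four modifications: midranks
#' break ties in the genetic scores; the p-value is two-sided; the p-value
#' is estimated directly from the permutation distribution of the case
#' rank-sum `W` using `|W - Wbar|`, where `Wbar` is the mean of `W` over the
#' `m` permutations; and missing genotypes are excluded from the control MAF
#' estimate and contribute 0 to an individual's score (equivalent to summing
#' over non-missing genotypes only).
#'
#' Per variant `j`, the control-based frequency estimate is
#' `q_j = (m_j^U + 1) / (2 n_j^U + 2)`, with `m_j^U` the minor-allele count
#' among controls with an observed genotype and `n_j^U` the number of such
#' controls; the weight is `w_j = sqrt(n_j q_j (1 - q_j))` where `n_j`
#' counts individuals with an observed genotype at `j` (set
#' `weight_n = "controls"` for the variant counting controls only).  An
#' individual's genetic score is `sum_j G_ij / w_j` over observed genotypes;
#' `W` is the sum of case midranks of the scores.
#'
#' Because the weights depend on control genotypes, they are recomputed
#' inside every permutation by default; `recompute_weights = FALSE` freezes
#' them at their observed-data values.
#'
#' Sample-monomorphic variants are excluded, consistent with the other
#' tests in the package.
#'
#' @param gd a [genotype_dataset()].
#' @param m number of permutations (default 10,000).
#' @param seed RNG seed (required).
#' @param recompute_weights recompute weights under each permutation.
#' @param weight_n `"all"` (default) or `"controls"`: which individuals
#'   `n_j` in the weight counts.
#' @param block permutations per matrix block.
#' @param keep_null keep the permutation `W` values.
#' @return an [rv_test] with `statistic = W_obs`, `p.value`, and extra
#'   fields `W_bar` and optionally `null`.
#' @export
wss_test <- function(gd, m = 10000L, seed, recompute_weights = TRUE,
                     weight_n = c("all", "controls"), block = 1000L,
                     keep_null = FALSE) {
  stopifnot(inherits(gd, "genotype_dataset"), m >= 1)
  if (missing(seed)) stop("a seed is required for permutation inference")
  weight_n <- match.arg(weight_n)
  if (gd$R == 0L || gd$S == 0L)
    stop("both cases and controls are required")
  pre <- .scan_precompute(gd$genotypes)
  keep <- pre$poly
  if (!any(keep))
    return(rv_test("WSS", NA_real_, NA_real_, v = 0L, m = m, valid = FALSE,
                   reason = "no polymorphic variants"))
  G0 <- pre$G0[, keep, drop = FALSE]
  M <- pre$M[, keep, drop = FALSE]
  n_obs <- pre$n_obs[keep]
  g_sum <- pre$g_sum[keep]
  y <- as.double(gd$case)

  w_stat <- function(Y) {
    # Y: N x b matrix of 0/1 labels; returns b-vector of case rank sums
    R_obs <- crossprod(M, Y)              # controls observed = n_obs - R_obs
    case_g <- crossprod(G0, Y)
    m_U <- g_sum - case_g                 # minor alleles among observed controls
    n_U <- n_obs - R_obs
    q <- (m_U + 1) / (2 * n_U + 2)
    n_w <- if (weight_n == "all") n_obs else n_U
    w <- sqrt(n_w * q * (1 - q))
    scores <- G0 %*% (1 / w)              # N x b
    ranks <- apply(scores, 2L, rank)      # midranks
    colSums(ranks * Y)
  }
  w_stat_frozen <- function(Y, inv_w) {
    scores <- as.vector(G0 %*% inv_w)
    ranks <- rank(scores)
    as.vector(crossprod(Y, ranks))
  }

  W_obs <- w_stat(matrix(y, ncol = 1))[1]
  inv_w_obs <- NULL
  if (!recompute_weights) {
    R_obs <- as.vector(crossprod(M, y))
    case_g <- as.vector(crossprod(G0, y))
    m_U <- g_sum - case_g
    n_U <- n_obs - R_obs
    q <- (m_U + 1) / (2 * n_U + 2)
    n_w <- if (weight_n == "all") n_obs else n_U
    inv_w_obs <- 1 / sqrt(n_w * q * (1 - q))
  }

  restore <- .with_seed(seed)
  on.exit(restore())
  W_perm <- numeric(m)
  done <- 0L
  while (done < m) {
    b <- min(block, m - done)
    Y <- vapply(seq_len(b), function(t) y[sample.int(gd$N)], numeric(gd$N))
    W_perm[done + seq_len(b)] <-
      if (recompute_weights) w_stat(Y) else w_stat_frozen(Y, inv_w_obs)
    done <- done + b
  }
  W_bar <- mean(W_perm)
  p <- (sum(abs(W_perm - W_bar) >= abs(W_obs - W_bar)) + 1) / (m + 1)
  rv_test("WSS", statistic = W_obs, p.value = p, v = sum(keep), m = m,
          extra = c(list(W_bar = W_bar),
                    if (keep_null) list(null = W_perm) else list()))
}
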