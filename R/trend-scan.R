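#' Per-variant Cochran-Armitage trend scan
#'
#' Computes the single-variant trend chi-square `T = N^O * rho^2` for every
#' variant, where `N^O` is the number of individuals with an observed
#' genotype at the variant and `rho` the Pearson correlation between the
#' minor-allele count and case status over those individuals.  Variants that
#' are monomorphic among the observed genotypes are excluded from the scan.
#'
#' @param gd a [genotype_dataset()].
#' @return data frame with one row per retained variant: `variant` (column
#'   index), `id`, `n_obs`, `U`, `var0`, `T`.
#' @export
trend_scan <- function(gd) {
  stopifnot(inherits(gd, "genotype_dataset"))
  pre <- .scan_precompute(gd$genotypes)
  st <- .scan_stats(pre, gd$case)
  keep <- pre$poly & st$var0 > 0
  data.frame(
    variant = which(keep),
    id = gd$variant_meta$id[keep],
    n_obs = pre$n_obs[keep],
    U = st$U[keep],
    var0 = st$var0[keep],
    T = st$U[keep]^2 / st$var0[keep],
    stringsAsFactors = FALSE
  )
}

# Label-independent per-variant quantities, computed once and reused across
# permutations: observation mask, genotype sums, and the polymorphic-among-
# observed filter (genotype variance over observed individuals > 0).
.scan_precompute <- function(G) {
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0L
  storage.mode(G0) <- "double"
  storage.mode(M) <- "double"
  n_obs <- colSums(M)
  g_sum <- colSums(G0)
  g2_sum <- colSums(G0^2)
  ssq <- n_obs * g2_sum - g_sum^2   # N * sum(g^2) - (sum g)^2, >0 iff polymorphic
  list(G0 = G0, M = M, n_obs = n_obs, g_sum = g_sum, g2_sum = g2_sum,
       poly = n_obs > 0 & ssq > 0, ssq = ssq)
}

# Per-variant U and Var0 for one label vector (or a matrix of label columns,
# in which case v x m matrices are returned).  Derived from the generalized
# statistic with additive scores, restricted to observed individuals.
.scan_stats <- function(pre, y) {
  if (is.matrix(y)) {
    R <- crossprod(pre$M, y)                # v x m observed cases
    case_g <- crossprod(pre$G0, y)          # v x m minor alleles in cases
  } else {
    R <- as.vector(crossprod(pre$M, y))
    case_g <- as.vector(crossprod(pre$G0, y))
  }
  S <- pre$n_obs - R
  U <- (S * case_g - R * (pre$g_sum - case_g)) / pre$n_obs
  var0 <- R * S / pre$n_obs^3 * pre$ssq
  list(U = U, var0 = var0, R = R, S = S)
}

# T matrix for permuted labels; variants where Var0 = 0 under a given
# permutation (all observed individuals in one group) contribute 0.
.scan_T <- function(pre, Y) {
  st <- .scan_stats(pre, Y)
  T <- st$U^2 / st$var0
  T[!is.finite(T)] <- 0
  T
}

#' Bonferroni-corrected maximum trend test (BC-CA)
#'
#' Rejects at level `alpha` when the maximum single-variant trend chi-square
#' over the locus reaches the Bonferroni-corrected quantile of its asymptotic
#' null distribution, `qchisq(1 - alpha / v, df = 1)`, where `v` is the
#' number of polymorphic variants in the dataset.  This is a decision test;
#' the Bonferroni-adjusted p-value `min(1, v * P(chisq_1 >= max T))` is
#' reported for convenience.
#'
#' @param x a [genotype_dataset()] or the data frame returned by
#'   [trend_scan()].
#' @param alpha type I error level.
#' @return an [rv_test] result with fields `statistic` (max T), `critical`,
#'   `reject`, `p.value` (Bonferroni-adjusted), `v`.
#' @export
bcca_test <- function(x, alpha = 0.05) {
  scan <- if (inherits(x, "genotype_dataset")) trend_scan(x) else x
  v <- nrow(scan)
  if (v == 0)
    return(rv_test("BC-CA", NA_real_, NA_real_, v = 0L, valid = FALSE,
                   reason = "no polymorphic variants"))
  max_T <- max(scan$T)
  critical <- stats::qchisq(1 - alpha / v, df = 1)
  p_adj <- min(1, v * stats::pchisq(max_T, df = 1, lower.tail = FALSE))
  rv_test("BC-CA", statistic = max_T, p.value = p_adj, v = v,
          extra = list(critical = critical, reject = max_T >= critical,
                       alpha = alpha))
}
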