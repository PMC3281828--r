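#' Build the CMC observation vectors and usability mask
#'
#' Splits variants at the pooled-sample MAF threshold (computed over observed
#' genotypes; sample-monomorphic variants are excluded from the test
#' entirely).  Rare variants are collapsed into an indicator equal to 1 when
#' any minor allele is present; common variants keep their minor-allele
#' counts.  An individual is unusable when (a) any common-variant genotype is
#' missing, or (b) no minor allele is observed at any rare variant while at
#' least one rare genotype is missing, which makes the indicator coding
#' ambiguous.
#'
#' @param gd a [genotype_dataset()].
#' @param rare_maf rare/common split: pooled-sample MAF `<=` this value is
#'   rare (default 0.01).
#' @return list with `X` (usable individuals x vector columns), `case`
#'   (labels of usable individuals), `usable` (logical over all
#'   individuals), `n_excluded_common`, `n_excluded_ambiguous`,
#'   `rare_variants`, `common_variants`.
#' @export
cmc_vector <- function(gd, rare_maf = 0.01) {
  stopifnot(inherits(gd, "genotype_dataset"))
  sm <- sample_maf(gd)
  poly <- !is.na(sm$maf) & sm$maf > 0 & sm$maf < 1
  rare <- which(poly & sm$maf <= rare_maf)
  common <- which(poly & sm$maf > rare_maf)
  G <- gd$genotypes
  # (a) complete data required at all common variants
  miss_common <- if (length(common))
    rowSums(is.na(G[, common, drop = FALSE])) > 0 else rep(FALSE, gd$N)
  # (b) ambiguous rare indicator: no observed minor allele, >=1 missing rare
  if (length(rare)) {
    Gr <- G[, rare, drop = FALSE]
    any_minor <- rowSums(Gr > 0, na.rm = TRUE) > 0
    any_miss <- rowSums(is.na(Gr)) > 0
    ambiguous <- !any_minor & any_miss
    indicator <- as.numeric(any_minor)
  } else {
    ambiguous <- rep(FALSE, gd$N)
    indicator <- NULL
  }
  usable <- !miss_common & !ambiguous
  parts <- list()
  if (!is.null(indicator))
    parts$rare_indicator <- indicator[usable]
  if (length(common))
    parts$common <- G[usable, common, drop = FALSE]
  X <- if (length(parts)) do.call(cbind, unname(parts)) else NULL
  if (!is.null(X))
    colnames(X) <- c(if (!is.null(indicator)) "rare_indicator",
                     gd$variant_meta$id[common])
  list(
    X = X,
    case = gd$case[usable],
    usable = usable,
    n_excluded_common = sum(miss_common),
    n_excluded_ambiguous = sum(ambiguous & !miss_common),
    rare_variants = rare,
    common_variants = common
  )
}

#' Combined Multivariate and Collapsing (CMC) test
#'
#' Compares the mean of the vector formed by the rare-variant indicator and
#' the common-variant minor-allele counts between cases and controls with
#' Hotelling's T-squared, using the g2 generalized inverse of the pooled
#' within-group covariance matrix (classical two-sample form, denominator
#' `n - 2`).  Using any generalized inverse is equivalent to the statistic on
#' a full-rank subset of linearly independent columns, so the effective
#' dimension `v` is the rank reported by the sweep.  The p-value comes from
#' the `F(v, n - v - 1)` approximation to the scaled statistic.  Results with
#' effective denominator degrees of freedom `n - v - 1 <= 4` are flagged
#' invalid, as are datasets where no usable individuals remain in one of the
#' groups.
#'
#' @param gd a [genotype_dataset()].
#' @param rare_maf rare/common MAF split (pooled sample, default 0.01).
#' @param tol pivot tolerance for the sweep (see [g2_sweep_inverse()]).
#' @return an [rv_test] with extra fields `v_effective`, `ddf`, `n_used`,
#'   `n_excluded_common`, `n_excluded_ambiguous`, `F`.
#' @export
cmc_test <- function(gd, rare_maf = 0.01, tol = 1e-8) {
  cv <- cmc_vector(gd, rare_maf)
  excl <- list(n_excluded_common = cv$n_excluded_common,
               n_excluded_ambiguous = cv$n_excluded_ambiguous)
  n <- length(cv$case)
  n1 <- sum(cv$case == 1L); n2 <- sum(cv$case == 0L)
  if (is.null(cv$X) || ncol(cv$X) == 0L || n1 == 0L || n2 == 0L || n < 3L) {
    return(rv_test("CMC", NA_real_, NA_real_, valid = FALSE,
                   reason = "no complete data",
                   extra = c(list(v_effective = NA_integer_, ddf = NA_real_,
                                  n_used = n, F = NA_real_), excl)))
  }
  X1 <- cv$X[cv$case == 1L, , drop = FALSE]
  X2 <- cv$X[cv$case == 0L, , drop = FALSE]
  d <- colMeans(X1) - colMeans(X2)
  S1 <- if (n1 > 1) stats::cov(X1) else matrix(0, ncol(cv$X), ncol(cv$X))
  S2 <- if (n2 > 1) stats::cov(X2) else matrix(0, ncol(cv$X), ncol(cv$X))
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n - 2)
  sw <- g2_sweep_inverse(Sp, tol = tol)
  v <- sw$rank
  if (v == 0L) {
    return(rv_test("CMC", NA_real_, NA_real_, valid = FALSE,
                   reason = "degenerate covariance",
                   extra = c(list(v_effective = 0L, ddf = NA_real_,
                                  n_used = n, F = NA_real_), excl)))
  }
  T2 <- (n1 * n2 / n) * drop(t(d) %*% sw$G %*% d)
  ddf <- n - v - 1
  Fstat <- if (ddf > 0) (ddf / ((n - 2) * v)) * T2 else NA_real_
  p <- if (ddf > 0) stats::pf(Fstat, v, ddf, lower.tail = FALSE) else NA_real_
  rv_test("CMC", statistic = T2, p.value = p, v = v,
          valid = ddf > 4,
          reason = if (ddf > 4) NA_character_ else "effective ddf <= 4",
          extra = c(list(v_effective = v, ddf = ddf, n_used = n, F = Fstat),
                    excl))
}
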