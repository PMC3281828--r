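#' Permutation tests on the maximum or sum of trend chi-squares
#'
#' Locus-wide inference from the permutation null distribution of a summary
#' of the per-variant Cochran-Armitage trend chi-square statistics: the
#' maximum (`"max"`, the CA max test) or the sum (`"sum"`, the CA sum test).
#' Case/control labels are shuffled over individuals; each individual's
#' genotype row, including its missingness pattern, stays fixed, which is the
#' exchangeability required for validity when genotypes are missing
#' completely at random.  Within each permutation the full trend scan is
#' recomputed; per-variant denominators and the monomorphic-exclusion set
#' depend only on genotypes, so they are precomputed once.
#'
#' The two-sided p-value is the add-one permutation estimator
#' `p = (#\{t : Q_t >= Q_obs\} + 1) / (m + 1)`, with ties counting toward
#' the tail, so `p` is bounded below by `1/(m + 1)`.
#'
#' When both summaries are requested, one shared stream of label shuffles
#' evaluates both (each p-value uses only its own statistic's null).
#'
#' @param gd a [genotype_dataset()].
#' @param summary `"max"`, `"sum"`, or both.
#' @param m number of permutations (default 10,000).
#' @param seed RNG seed (required, for reproducibility).
#' @param block permutations per matrix block (memory/speed trade-off).
#' @param keep_null keep the per-permutation statistic values in the result.
#' @return a single [rv_test] when one summary is requested, otherwise a
#'   named list of them.  Each carries `v`, `m` and (optionally) `null`.
#' @export
ca_perm_test <- function(gd, summary = c("max", "sum"), m = 10000L, seed,
                         block = 1000L, keep_null = FALSE) {
  stopifnot(inherits(gd, "genotype_dataset"), m >= 1)
  summary <- match.arg(summary, several.ok = TRUE)
  if (missing(seed)) stop("a seed is required for permutation inference")
  if (gd$R == 0L || gd$S == 0L)
    stop("both cases and controls are required")
  pre <- .scan_precompute(gd$genotypes)
  keep <- pre$poly
  v <- sum(keep)
  if (v == 0L) {
    out <- lapply(summary, function(s)
      rv_test(paste0("CA ", s), NA_real_, NA_real_, v = 0L, m = m,
              valid = FALSE, reason = "no polymorphic variants"))
    names(out) <- summary
    return(if (length(out) == 1L) out[[1L]] else out)
  }
  pre <- lapply(pre, function(x) if (is.matrix(x)) x[, keep, drop = FALSE]
                                 else if (length(x) > 1L) x[keep] else x)
  T_obs <- .scan_T(pre, as.double(gd$case))
  q_obs <- c(max = max(T_obs), sum = sum(T_obs))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  q_perm <- matrix(NA_real_, nrow = m, ncol = 2,
                   dimnames = list(NULL, c("max", "sum")))
  done <- 0L
  y <- as.double(gd$case)
  while (done < m) {
    b <- min(block, m - done)
    Y <- vapply(seq_len(b), function(t) y[sample.int(gd$N)], numeric(gd$N))
    Tm <- .scan_T(pre, Y)                      # v x b
    q_perm[done + seq_len(b), "max"] <- apply(Tm, 2L, max)
    q_perm[done + seq_len(b), "sum"] <- colSums(Tm)
    done <- done + b
  }
  out <- lapply(summary, function(s) {
    p <- (sum(q_perm[, s] >= q_obs[[s]]) + 1) / (m + 1)
    rv_test(paste0("CA ", s), statistic = q_obs[[s]], p.value = p,
            v = v, m = m,
            extra = if (keep_null) list(null = q_perm[, s]) else list())
  })
  names(out) <- summary
  if (length(out) == 1L) out[[1L]] else out
}

#' SKAT-style weighted sum of squared score statistics
#'
#' `Q = sum_j w_j U_j^2` over polymorphic variants, where `U_j` is the
#' single-variant additive score statistic and the `U_j` and their estimated
#' null variances are computed from all available genotypes at each variant.
#' With `w_j = 1 / Var0(U_j)` the statistic equals the sum of trend
#' chi-squares (the CA sum statistic) exactly, including under missing data;
#' with `w_j = 1` it is the C-alpha statistic form.
#'
#' @param gd a [genotype_dataset()].
#' @param weights `"invvar"`, `"one"`, or a numeric vector over the retained
#'   (polymorphic) variants.
#' @return list with `Q`, the per-variant `U`, `var0`, `weights`, and the
#'   retained variant indices.
#' @export
skat_statistic <- function(gd, weights = c("invvar", "one")) {
  scan <- trend_scan(gd)
  if (nrow(scan) == 0L) stop("no polymorphic variants")
  w <- if (is.character(weights)) {
    switch(match.arg(weights),
           invvar = 1 / scan$var0,
           one = rep(1, nrow(scan)))
  } else {
    if (length(weights) != nrow(scan))
      stop("need one weight per retained variant")
    weights
  }
  if (any(w < 0)) stop("weights must be nonnegative")
  if (all(w == 0)) stop("all weights are zero")
  list(Q = sum(w * scan$U^2), U = scan$U, var0 = scan$var0,
       weights = w, variant = scan$variant)
}

#' Beta-density MAF weights
#'
#' Optional SKAT-style weights: the squared Beta(`a`, `b`) density evaluated
#' at the pooled-sample MAF of each polymorphic variant, upweighting rare
#' variants.  Provided as a helper only; the validated default weighting in
#' this package is inverse null variance (see [skat_statistic()]).
#'
#' @param gd a [genotype_dataset()].
#' @param a,b Beta shape parameters (conventionally 1 and 25).
#' @return numeric weight vector over the variants retained by [trend_scan()].
#' @export
skat_beta_weights <- function(gd, a = 1, b = 25) {
  scan <- trend_scan(gd)
  maf <- sample_maf(gd)$maf[scan$variant]
  stats::dbeta(maf, a, b)^2
}

# Evaluate expr-free seeding: set the RNG to `seed` and return a restorer.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
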