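#' Construct a haplotype population
#'
#' A haplotype population is a set of `n_hap` binary haplotypes over `v`
#' segregating sites at a locus of `locus_length_bp` base pairs.  Allele 1 is
#' the derived (mutant) allele under the infinite-sites convention used by
#' coalescent simulators; the minor allele at each site is determined from the
#' population allele frequencies (see [minor_alleles()]).
#'
#' Variant positions live on the unit interval, i.e. as fractions of the locus
#' length, exactly as coalescent simulators emit them.  They are kept on that
#' scale throughout because the missing-genotype process is defined on it;
#' conversion to base pairs is for reporting only.
#'
#' @param haplotypes integer or logical matrix, `n_hap x v`, entries 0/1.
#' @param positions numeric vector of length `v`, sorted, in `[0, 1]`.
#' @param locus_length_bp locus length in base pairs.
#' @return An object of class `haplotype_population` with fields
#'   `haplotypes`, `positions`, `locus_length_bp`, `pop_allele_freq`
#'   (per-site frequency of allele 1) and `minor_allele` (0 or 1).
#' @export
haplotype_population <- function(haplotypes, positions, locus_length_bp) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  v <- ncol(haplotypes)
  if (length(positions) != v)
    stop("length(positions) must equal ncol(haplotypes)")
  if (v > 0) {
    if (!all(haplotypes %in% c(0L, 1L)))
      stop("haplotype entries must be 0 or 1")
    if (any(positions < 0 | positions > 1))
      stop("positions must lie in [0, 1]")
    if (is.unsorted(positions))
      stop("positions must be non-decreasing")
    freq <- colMeans(haplotypes)
    if (any(freq <= 0 | freq >= 1))
      stop("all variants must be polymorphic in the population")
  } else {
    freq <- numeric(0)
  }
  structure(
    list(
      haplotypes = haplotypes,
      positions = as.numeric(positions),
      locus_length_bp = as.integer(locus_length_bp),
      pop_allele_freq = freq,
      # frequency ties at 0.5 declare the derived allele (1) minor, so that
      # the coding is deterministic and matches simulator output orientation
      minor_allele = ifelse(freq <= 0.5, 1L, 0L)
    ),
    class = "haplotype_population"
  )
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat("Haplotype population:", nrow(x$haplotypes), "haplotypes,",
      ncol(x$haplotypes), "segregating sites,",
      x$locus_length_bp, "bp locus\n")
  if (ncol(x$haplotypes) > 0) {
    maf <- pmin(x$pop_allele_freq, 1 - x$pop_allele_freq)
    cat(sprintf("  MAF: median %.4g, %d sites with MAF <= 0.01\n",
                stats::median(maf), sum(maf <= 0.01)))
  }
  invisible(x)
}

#' Minor allele frequency and minor-allele coding
#'
#' The minor allele at each site is the allele with population frequency
#' below 0.5; an exact tie is broken in favour of allele 1 (derived).
#'
#' @param pop a [haplotype_population()].
#' @return data frame with columns `freq1` (frequency of allele 1),
#'   `maf` in `(0, 0.5]` and `minor_allele` (0 or 1).
#' @export
minor_alleles <- function(pop) {
  stopifnot(inherits(pop, "haplotype_population"))
  if (ncol(pop$haplotypes) == 0)
    stop("population has no variants")
  f <- pop$pop_allele_freq
  data.frame(freq1 = f, maf = pmin(f, 1 - f), minor_allele = pop$minor_allele)
}

#' Minor-allele indicator matrix
#'
#' Recode haplotypes so that 1 marks the minor allele at every site, per the
#' population-based coding in [minor_alleles()].
#'
#' @param pop a [haplotype_population()].
#' @return integer matrix of the same dimension as `pop$haplotypes`.
#' @export
minor_haplotypes <- function(pop) {
  H <- pop$haplotypes
  flip <- pop$minor_allele == 0L
  if (any(flip)) H[, flip] <- 1L - H[, flip]
  H
}

#' Pairwise linkage disequilibrium correlation
#'
#' Haplotype-count correlation coefficient `r` between the minor alleles of
#' two variants: \eqn{r = D / \sqrt{p_i (1 - p_i) p_j (1 - p_j)}} with
#' `D = freq(minor_i, minor_j) - p_i p_j`.  This equals the Pearson
#' correlation of the minor-allele indicator columns and, by symmetry, the
#' major-allele correlation.
#'
#' @param pop a [haplotype_population()].
#' @param i,j variant column indices.
#' @return numeric scalar in `[-1, 1]`.
#' @export
pairwise_r <- function(pop, i, j) {
  stopifnot(inherits(pop, "haplotype_population"))
  H <- pop$haplotypes
  hi <- H[, i]; hj <- H[, j]
  if (pop$minor_allele[i] == 0L) hi <- 1L - hi
  if (pop$minor_allele[j] == 0L) hj <- 1L - hj
  pi <- mean(hi); pj <- mean(hj)
  if (pi <= 0 || pi >= 1 || pj <= 0 || pj >= 1)
    stop("both variants must be polymorphic")
  D <- mean(hi * hj) - pi * pj
  D / sqrt(pi * (1 - pi) * pj * (1 - pj))
}

#' Attainable range of the LD correlation for given allele frequencies
#'
#' For two variants with minor allele frequencies `p1` and `p2`, the LD
#' coefficient `D` between the minor alleles is bounded by
#' `max(-p1 p2, -(1-p1)(1-p2)) <= D <= min(p1 (1-p2), (1-p1) p2)`, which
#' bounds `r` accordingly.  For two equally rare variants (`p1 = p2 = p`)
#' the lower bound is `r_min = -p / (1 - p)`: e.g. two variants with MAF
#' 0.01 can never be more negatively correlated than -0.0101.
#'
#' @param p1,p2 minor allele frequencies in `(0, 0.5]`.
#' @return list with `D_min`, `D_max`, `r_min`, `r_max`.
#' @export
ld_r_bounds <- function(p1, p2 = p1) {
  stopifnot(p1 > 0, p1 <= 0.5, p2 > 0, p2 <= 0.5)
  D_min <- max(-p1 * p2, -(1 - p1) * (1 - p2))
  D_max <- min(p1 * (1 - p2), (1 - p1) * p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  list(D_min = D_min, D_max = D_max,
       r_min = D_min / denom, r_max = D_max / denom)
}
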