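#' Construct a case-control genotype dataset
#'
#' Genotypes are minor-allele counts (0, 1, 2) per individual and biallelic
#' variant; missing genotypes are stored as `NA` (an out-of-band sentinel --
#' 0 is a valid genotype, and any missing-to-zero recoding is a property of
#' individual tests, never of storage).  The minor allele is with respect to
#' the coding recorded in `variant_meta`, which is population-based when the
#' dataset was drawn from a known haplotype population.
#'
#' @param genotypes integer matrix, `N x v`, entries in `{0, 1, 2, NA}`.
#' @param case integer/logical vector of length `N`; 1 = case, 0 = control.
#' @param variant_meta optional data frame with one row per variant; columns
#'   `id`, `position` (on the unit interval), `pop_maf`, `minor_source` are
#'   filled with defaults when absent.
#' @param locus_length_bp optional locus length in base pairs (needed by the
#'   missingness model, which works on positions rescaled by locus length).
#' @return An object of class `genotype_dataset` with fields `genotypes`,
#'   `case`, `variant_meta`, `locus_length_bp` and counts `R`, `S`, `N`.
#' @export
genotype_dataset <- function(genotypes, case, variant_meta = NULL,
                             locus_length_bp = NA_integer_) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  case <- as.integer(case)
  if (length(case) != nrow(genotypes))
    stop("length(case) must equal nrow(genotypes)")
  if (!all(case %in% c(0L, 1L)))
    stop("case labels must be 0 (control) or 1 (case)")
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotype entries must be 0, 1, 2 or NA")
  v <- ncol(genotypes)
  if (is.null(variant_meta)) {
    variant_meta <- data.frame(
      id = if (is.null(colnames(genotypes))) paste0("v", seq_len(v))
           else colnames(genotypes),
      position = rep(NA_real_, v),
      pop_maf = rep(NA_real_, v),
      minor_source = rep("sample", v),
      stringsAsFactors = FALSE
    )
  } else {
    variant_meta <- as.data.frame(variant_meta)
    if (nrow(variant_meta) != v)
      stop("variant_meta must have one row per variant")
    for (col in c("id", "position", "pop_maf", "minor_source")) {
      if (is.null(variant_meta[[col]])) {
        variant_meta[[col]] <- switch(col,
          id = paste0("v", seq_len(v)),
          position = NA_real_, pop_maf = NA_real_, minor_source = "sample")
      }
    }
  }
  colnames(genotypes) <- variant_meta$id
  structure(
    list(
      genotypes = genotypes,
      case = case,
      variant_meta = variant_meta,
      locus_length_bp = as.integer(locus_length_bp),
      R = sum(case == 1L),
      S = sum(case == 0L),
      N = length(case)
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", x$N, "individuals (", x$R, "cases /", x$S,
      "controls ),", ncol(x$genotypes), "variants\n")
  n_miss <- sum(is.na(x$genotypes))
  if (n_miss > 0)
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n", n_miss,
                100 * n_miss / length(x$genotypes)))
  invisible(x)
}

#' Pooled-sample minor allele frequency
#'
#' Frequency of the coded (minor) allele over observed genotypes in the
#' pooled case-control sample, and the corresponding sample MAF
#' `min(f, 1 - f)`.  Variants with no observed genotypes get `NA`.
#'
#' @param gd a [genotype_dataset()].
#' @return data frame with columns `coded_freq`, `maf`, `n_obs`.
#' @export
sample_maf <- function(gd) {
  G <- gd$genotypes
  n_obs <- colSums(!is.na(G))
  f <- colSums(G, na.rm = TRUE) / (2 * n_obs)
  f[n_obs == 0] <- NA_real_
  data.frame(coded_freq = f, maf = pmin(f, 1 - f), n_obs = n_obs)
}
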