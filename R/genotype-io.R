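#' Read and write genotype datasets as delimited text
#'
#' The matrix format is tab-delimited with a header row: columns
#' `sample_id`, `case`, then one column per variant holding minor-allele
#' counts with `NA` for missing genotypes.  Round-trips are lossless for
#' genotypes, missingness and case labels.
#'
#' @param gd a [genotype_dataset()].
#' @param file path.
#' @return `write_genotype_matrix` returns `file` invisibly;
#'   `read_genotype_matrix` returns a [genotype_dataset()].
#' @export
write_genotype_matrix <- function(gd, file) {
  df <- data.frame(
    sample_id = if (is.null(rownames(gd$genotypes)))
      paste0("ind", seq_len(gd$N)) else rownames(gd$genotypes),
    case = gd$case,
    as.data.frame(gd$genotypes),
    check.names = FALSE
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "case") %in% names(df)))
    stop("expected 'sample_id' and 'case' columns")
  G <- as.matrix(df[, setdiff(names(df), c("sample_id", "case")), drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df$sample_id
  genotype_dataset(G, df$case)
}

#' Write a genotype dataset as VCF plus a phenotype sidecar
#'
#' Emits a minimal VCFv4.2 file with unphased diploid GT fields ("./." for
#' missing) and an `MA` INFO tag recording whether the minor allele is the
#' REF or ALT allele, plus a tab-delimited phenotype file (`sample_id`,
#' `case`).  The ALT allele carries the minor-allele coding by default, so a
#' genotype count of 2 becomes "1/1".
#'
#' @param gd a [genotype_dataset()].
#' @param file VCF output path.
#' @param pheno_file phenotype sidecar path; default `file` + ".pheno".
#' @return `file`, invisibly.
#' @export
write_vcf_dataset <- function(gd, file, pheno_file = paste0(file, ".pheno")) {
  G <- gd$genotypes
  v <- ncol(G); n <- nrow(G)
  samples <- if (is.null(rownames(G))) paste0("ind", seq_len(n)) else rownames(G)
  pos_bp <- gd$variant_meta$position
  pos_bp <- if (all(is.na(pos_bp))) seq_len(v)
            else pmax(1L, floor(pos_bp * max(1L, gd$locus_length_bp, na.rm = TRUE)))
  gt_of <- function(g) c("0/0", "0/1", "1/1")[g + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MA,Number=1,Type=String,Description=\"Minor allele (REF or ALT)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(v), function(j) {
    gt <- ifelse(is.na(G[, j]), "./.", gt_of(G[, j]))
    paste(c("1", pos_bp[j], gd$variant_meta$id[j], "A", "C", ".", "PASS",
            "MA=ALT", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
  utils::write.table(data.frame(sample_id = samples, case = gd$case),
                     pheno_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a genotype dataset from VCF plus a phenotype sidecar
#'
#' Parses diploid unphased GT fields into minor-allele counts.  Multi-allelic
#' records are rejected (the methods here are defined for biallelic variants
#' only).  The minor allele is taken from the `MA` INFO tag when present;
#' otherwise the allele with sample frequency below 0.5 is declared minor, so
#' a record whose ALT allele is the major allele has its counts flipped
#' (`1/1` becomes 0 minor alleles).
#'
#' @param file VCF path.
#' @param pheno_file phenotype sidecar path (`sample_id`, `case`).
#' @return a [genotype_dataset()].
#' @export
read_vcf_dataset <- function(file, pheno_file = paste0(file, ".pheno")) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(s) {
    if (is.na(s)) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  A <- t(apply(gt, 1L, function(row) vapply(row, alt_count, integer(1))))
  if (nrow(gt) == 1L) A <- matrix(A, nrow = 1L, dimnames = dimnames(gt))
  ma <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    hit <- regmatches(fix$INFO, regexpr("MA=[A-Z]+", fix$INFO))
    ma[grepl("MA=", fix$INFO)] <- sub("MA=", "", hit)
  }
  G <- matrix(NA_integer_, nrow = ncol(A), ncol = nrow(A))
  for (j in seq_len(nrow(A))) {
    counts <- A[j, ]
    minor_is_alt <- if (!is.na(ma[j])) ma[j] == "ALT"
      else mean(counts, na.rm = TRUE) / 2 <= 0.5
    G[, j] <- if (minor_is_alt) counts else 2L - counts
  }
  colnames(G) <- fix$ID
  rownames(G) <- colnames(A)
  ph <- utils::read.delim(pheno_file, stringsAsFactors = FALSE)
  idx <- match(rownames(G), ph$sample_id)
  if (anyNA(idx)) stop("phenotype file does not cover all VCF samples")
  genotype_dataset(G, ph$case[idx])
}
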