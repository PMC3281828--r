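#' Read Hudson ms-style simulator output
#'
#' Parses the standard text dialect of Hudson's \code{ms} coalescent
#' simulator: replicates delimited by \code{//}, a \code{segsites:} line, a
#' \code{positions:} line of values on the unit interval, then one 0/1 string
#' per haplotype.  A \code{segsites: 0} replicate yields a population with
#' zero variants.
#'
#' @param file path to an ms output file, or a character vector of lines.
#' @param locus_length_bp locus length in base pairs to record on each
#'   population (the ms format itself carries only rescaled positions).
#' @return list of [haplotype_population()] objects, one per replicate.
#' @export
read_ms <- function(file, locus_length_bp = 1L) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  starts <- grep("^//", lines)
  if (length(starts) == 0L) stop("no '//' replicate delimiters found")
  bounds <- c(starts, length(lines) + 1L)
  pops <- vector("list", length(starts))
  for (rep in seq_along(starts)) {
    block <- lines[(bounds[rep] + 1L):(bounds[rep + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    seg_line <- grep("^segsites:", block, value = TRUE)
    if (length(seg_line) != 1L) stop("replicate ", rep, ": missing segsites line")
    segsites <- as.integer(sub("^segsites:\\s*", "", seg_line))
    if (segsites == 0L) {
      pops[[rep]] <- haplotype_population(
        matrix(integer(0), nrow = 0, ncol = 0), numeric(0), locus_length_bp)
      attr(pops[[rep]], "empty") <- TRUE
      next
    }
    pos_line <- grep("^positions:", block, value = TRUE)
    if (length(pos_line) != 1L) stop("replicate ", rep, ": missing positions line")
    positions <- as.numeric(strsplit(trimws(
      sub("^positions:\\s*", "", pos_line)), "\\s+")[[1]])
    if (length(positions) != segsites)
      stop("replicate ", rep, ": positions count != segsites")
    hap_lines <- block[grepl("^[01]+$", block)]
    if (length(hap_lines) == 0L) stop("replicate ", rep, ": no haplotype rows")
    if (any(nchar(hap_lines) != segsites))
      stop("replicate ", rep, ": haplotype line length != segsites")
    H <- matrix(as.integer(unlist(strsplit(hap_lines, ""), use.names = FALSE)),
                nrow = length(hap_lines), byrow = TRUE)
    pops[[rep]] <- haplotype_population(H, positions, locus_length_bp)
  }
  pops
}

#' Write haplotype populations in ms format
#'
#' @param pops a [haplotype_population()] or list of them.
#' @param file output path.
#' @param digits decimal digits for positions (ms itself prints 4; the
#'   default of 6 keeps round-trips through [read_ms()] faithful for
#'   populations with many variants).
#' @return `file`, invisibly.
#' @export
write_ms <- function(pops, file, digits = 6L) {
  if (inherits(pops, "haplotype_population")) pops <- list(pops)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ms-format output", "0 0 0"), con)
  for (pop in pops) {
    v <- ncol(pop$haplotypes)
    writeLines(c("", "//", paste0("segsites: ", v)), con)
    if (v > 0) {
      writeLines(paste0("positions: ",
                        paste(formatC(pop$positions, digits = digits,
                                      format = "f"), collapse = " ")), con)
      writeLines(apply(pop$haplotypes, 1L, paste, collapse = ""), con)
    }
  }
  invisible(file)
}
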