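#' Association test result
#'
#' Light container for the outcome of a locus-wide association test:
#' statistic value, p-value (NA for pure decision tests), method name,
#' number of variants used, permutation count, and a validity flag with a
#' reason (e.g. insufficient denominator degrees of freedom).
#'
#' @param method method name.
#' @param statistic observed statistic value.
#' @param p.value p-value in `(0, 1]`, or `NA`.
#' @param v number of variants used.
#' @param m number of permutations, or `NA`.
#' @param valid logical validity flag.
#' @param reason reason when invalid.
#' @param extra named list of method-specific fields merged into the result.
#' @return object of class `rv_test`.
#' @name rv_test
#' @export
rv_test <- function(method, statistic, p.value = NA_real_, v = NA_integer_,
                    m = NA_integer_, valid = TRUE, reason = NA_character_,
                    extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, p.value = p.value,
           v = v, m = m, valid = valid, reason = reason), extra),
    class = "rv_test"
  )
}

#' @export
print.rv_test <- function(x, ...) {
  cat(x$method, "locus-wide association test\n")
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (!is.na(x$p.value)) cat(sprintf(", p = %.4g", x$p.value))
  cat("\n")
  if (!is.null(x$critical))
    cat(sprintf("  critical value = %.4f (alpha = %g), reject = %s\n",
                x$critical, x$alpha, x$reject))
  if (!is.na(x$v)) cat("  variants used:", x$v, "\n")
  if (!is.na(x$m)) cat("  permutations:", x$m, "\n")
  if (!x$valid) cat("  INVALID:", x$reason, "\n")
  invisible(x)
}
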