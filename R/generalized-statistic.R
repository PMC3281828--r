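#' Generalized score/trend statistic for multi-variant genotype classes
#'
#' For genotype classes `k` with case counts `r_k`, control counts `s_k`
#' (`n_k = r_k + s_k`, `R = sum r_k`, `S = sum s_k`, `N = R + S`) and scores
#' `X_k`, the score statistic and its estimated null variance are
#' \deqn{U = N^{-1} \sum_k X_k (S r_k - R s_k),}
#' \deqn{\widehat{Var}_0(U) = \frac{R S}{N^3}\left[N \sum_k X_k^2 n_k -
#'   \left(\sum_k X_k n_k\right)^2\right],}
#' and the chi-square statistic is `T = U^2 / Var0`, asymptotically
#' chi-square with 1 df under the null of equal class frequencies in cases
#' and controls.  With additive scores 0/1/2 on a single variant, `T` is the
#' classical Cochran-Armitage trend chi-square and equals `N * rho^2` where
#' `rho` is the Pearson correlation between genotype and case status.
#'
#' @param r_k,s_k per-class case and control counts.
#' @param scores per-class scores `X_k`.
#' @return list with `U`, `var0`, `T`, and `valid` (`FALSE` when the scores
#'   are constant over occupied classes, so that `Var0 = 0` and `T` is
#'   undefined).
#' @export
generalized_statistic <- function(r_k, s_k, scores) {
  if (length(r_k) != length(s_k) || length(r_k) != length(scores))
    stop("r_k, s_k and scores must have equal length")
  n_k <- r_k + s_k
  R <- sum(r_k); S <- sum(s_k); N <- R + S
  if (N == 0) stop("no observations")
  U <- sum(scores * (S * r_k - R * s_k)) / N
  var0 <- (R * S / N^3) * (N * sum(scores^2 * n_k) - sum(scores * n_k)^2)
  if (var0 <= 0) {
    list(U = U, var0 = var0, T = NA_real_, valid = FALSE)
  } else {
    list(U = U, var0 = var0, T = U^2 / var0, valid = TRUE)
  }
}

#' Score schemes over multi-variant genotype classes
#'
#' Maps a matrix of multi-variant genotype classes to scores: `trend`
#' uses the minor-allele count at one designated variant, `collapse` the
#' indicator of any minor allele over a designated variant set, and `sum`
#' the total minor-allele count.
#'
#' @param kind one of `"trend"`, `"collapse"`, `"sum"`.
#' @param variants for `trend`, the single variant index; for `collapse`,
#'   the indices of the designated (e.g. rare) variants, defaulting to all.
#' @return an object of class `score_scheme`; apply it to a class matrix
#'   (classes x variants) with [scheme_scores()].
#' @export
score_scheme <- function(kind = c("trend", "collapse", "sum"), variants = NULL) {
  kind <- match.arg(kind)
  if (kind == "trend" && length(variants) != 1L)
    stop("trend scheme needs exactly one variant index")
  structure(list(kind = kind, variants = variants), class = "score_scheme")
}

#' Evaluate a score scheme on genotype classes
#'
#' @param scheme a [score_scheme()].
#' @param classes matrix of genotype classes (rows = classes, columns =
#'   variants, entries = minor-allele counts 0/1/2).
#' @return numeric vector of per-class scores.
#' @export
scheme_scores <- function(scheme, classes) {
  classes <- as.matrix(classes)
  switch(scheme$kind,
    trend = classes[, scheme$variants],
    collapse = {
      cols <- if (is.null(scheme$variants)) seq_len(ncol(classes))
              else scheme$variants
      as.numeric(rowSums(classes[, cols, drop = FALSE]) > 0)
    },
    sum = rowSums(classes)
  )
}
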