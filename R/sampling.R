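#' Draw a case-control sample from a haplotype population
#'
#' Rejection sampling: two haplotypes are drawn with replacement (random
#' mating) to form an individual's multi-variant genotype; affection status
#' is assigned with probability equal to the genotype's penetrance; the
#' individual is kept while its group (case or control) is still short.
#' Sampling stops when exactly `R` cases and `S` controls have accumulated.
#' Genotypes are coded as minor-allele counts under the population-based
#' minor-allele coding, which is fixed before sampling so that data sets
#' drawn from the same population are comparable.
#'
#' @param pop a [haplotype_population()].
#' @param model a `disease_model` from [assign_disease_model()].
#' @param R,S numbers of cases and controls.
#' @param seed RNG seed.
#' @param max_draws cap on individual draws, guarding pathological models.
#' @return a [genotype_dataset()] with cases first.
#' @export
sample_case_control <- function(pop, model, R, S, seed = NULL,
                                max_draws = 1e7) {
  stopifnot(inherits(pop, "haplotype_population"),
            inherits(model, "disease_model"), R >= 1, S >= 1)
  if (!is.null(seed)) {
    restore <- .with_seed(seed)
    on.exit(restore())
  }
  Hm <- minor_haplotypes(pop)
  n_hap <- nrow(Hm)
  risk <- which(model$beta != 0)
  Hr <- Hm[, risk, drop = FALSE]
  br <- model$beta[risk]
  case_rows <- matrix(integer(0), nrow = 0, ncol = 2)
  ctrl_rows <- matrix(integer(0), nrow = 0, ncol = 2)
  drawn <- 0
  batch <- max(256L, 2L * ceiling((R + S) / max(model$f0, 1 - model$f0) / 8))
  while (nrow(case_rows) < R || nrow(ctrl_rows) < S) {
    if (drawn > max_draws)
      stop("case-control sampling exceeded max_draws; check the model")
    h1 <- sample.int(n_hap, batch, replace = TRUE)
    h2 <- sample.int(n_hap, batch, replace = TRUE)
    drawn <- drawn + batch
    pen <- stats::plogis(model$beta0 +
      as.vector((Hr[h1, , drop = FALSE] + Hr[h2, , drop = FALSE]) %*% br))
    is_case <- stats::runif(batch) < pen
    need_case <- R - nrow(case_rows)
    need_ctrl <- S - nrow(ctrl_rows)
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    case_rows <- rbind(case_rows, cbind(h1[take_case], h2[take_case]))
    ctrl_rows <- rbind(ctrl_rows, cbind(h1[take_ctrl], h2[take_ctrl]))
  }
  pairs <- rbind(case_rows, ctrl_rows)
  G <- Hm[pairs[, 1], , drop = FALSE] + Hm[pairs[, 2], , drop = FALSE]
  .dataset_from_pop(G, c(rep(1L, R), rep(0L, S)), pop)
}

#' Draw a cohort sample, assigning affection by penetrance
#'
#' Samples `n` individuals (2`n` haplotypes with replacement) and assigns
#' each affection status with probability equal to its penetrance, keeping
#' every individual regardless of outcome.  Useful for studying the sampling
#' process itself (e.g. how many population variants appear in a sample of a
#' given size).
#'
#' @param pop a [haplotype_population()].
#' @param n number of individuals.
#' @param model a `disease_model`, or `NULL` for a label-free draw (all
#'   labels 0).
#' @param seed RNG seed.
#' @return a [genotype_dataset()].
#' @export
sample_cohort <- function(pop, n, model = NULL, seed = NULL) {
  stopifnot(inherits(pop, "haplotype_population"), n >= 1)
  if (!is.null(seed)) {
    restore <- .with_seed(seed)
    on.exit(restore())
  }
  Hm <- minor_haplotypes(pop)
  h1 <- sample.int(nrow(Hm), n, replace = TRUE)
  h2 <- sample.int(nrow(Hm), n, replace = TRUE)
  G <- Hm[h1, , drop = FALSE] + Hm[h2, , drop = FALSE]
  label <- if (is.null(model)) rep(0L, n)
           else as.integer(stats::runif(n) < penetrance(G, model))
  .dataset_from_pop(G, label, pop)
}

.dataset_from_pop <- function(G, case, pop) {
  v <- ncol(G)
  meta <- data.frame(
    id = paste0("v", seq_len(v)),
    position = pop$positions,
    pop_maf = pmin(pop$pop_allele_freq, 1 - pop$pop_allele_freq),
    minor_source = "population",
    stringsAsFactors = FALSE
  )
  genotype_dataset(G, case, meta, locus_length_bp = pop$locus_length_bp)
}

#' Mask genotypes with a two-state Markov-chain missingness process
#'
#' For each individual independently, the sequence is traversed from
#' position 0 in the observed state `O`, alternating `O` intervals with
#' lengths distributed `Exp(L (1 - lambda))` and missing (`M`) intervals
#' with lengths distributed `Exp(L lambda)` on the unit-interval position
#' scale, where `lambda` is the per-base-pair call rate and `L` the locus
#' length.  Genotypes at variant positions not covered by an `O` interval
#' are set to missing.  The expected fraction of the sequence in `O` is
#' `lambda`, and the process is independent of genotypes and affection
#' status, so genotypes are missing completely at random.
#'
#' @param gd a [genotype_dataset()] whose `variant_meta$position` holds
#'   unit-interval positions.
#' @param call_rate per-base-pair call rate `lambda`, in `(0, 1]`.
#' @param locus_length_bp locus length; defaults to the dataset's.
#' @param seed RNG seed.
#' @return the dataset with masked entries set to `NA`.
#' @export
apply_missingness <- function(gd, call_rate, locus_length_bp = NULL,
                              seed = NULL) {
  stopifnot(inherits(gd, "genotype_dataset"),
            call_rate > 0, call_rate <= 1)
  if (call_rate == 1) return(gd)
  L <- if (is.null(locus_length_bp)) gd$locus_length_bp else locus_length_bp
  if (is.na(L) || L < 1) stop("locus length required for the missingness model")
  pos <- gd$variant_meta$position
  if (anyNA(pos)) stop("variant positions required for the missingness model")
  if (!is.null(seed)) {
    restore <- .with_seed(seed)
    on.exit(restore())
  }
  rate_o <- L * (1 - call_rate)   # O -> M transitions per unit position
  rate_m <- L * call_rate         # M -> O
  G <- gd$genotypes
  n_chunk <- max(16L, ceiling(2 * rate_o))
  for (i in seq_len(gd$N)) {
    # alternating O/M interval lengths, extended until the locus is covered
    lens <- numeric(0)
    total <- 0
    while (total <= 1) {
      o_len <- stats::rexp(n_chunk, rate_o)
      m_len <- stats::rexp(n_chunk, rate_m)
      lens <- c(lens, as.vector(rbind(o_len, m_len)))
      total <- sum(lens)
    }
    breaks <- cumsum(lens)
    idx <- findInterval(pos, breaks)        # 0 = first (O) interval
    missing_here <- idx %% 2L == 1L          # odd index = M interval
    if (any(missing_here)) G[i, missing_here] <- NA_integer_
  }
  genotype_dataset(G, gd$case, gd$variant_meta, gd$locus_length_bp)
}
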