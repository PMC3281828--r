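#' Define risk-variant classes by MAF range
#'
#' A risk class is a half-open population-MAF interval `[maf_lo, maf_hi)`
#' with an associated odds ratio applied per minor allele.
#'
#' @param maf_lo,maf_hi interval bounds.
#' @param or odds ratio for one additional minor allele.
#' @return one-row data frame; `rbind` rows to form a class set.
#' @export
risk_class <- function(maf_lo, maf_hi, or) {
  stopifnot(maf_lo >= 0, maf_hi > maf_lo, or > 0)
  data.frame(maf_lo = maf_lo, maf_hi = maf_hi, or = or)
}

#' Assign a logistic disease model to a haplotype population
#'
#' Disease risk for a multi-variant genotype is
#' `P(A | G) = logistic(beta0 + sum_j beta_j G_j)`, with `beta0 = logit(f0)`
#' the log odds of the wild-type penetrance and `G_j` minor-allele counts.
#' Risk variants are selected by rejection: repeatedly draw a uniformly
#' random variant; if its population MAF falls in some class interval
#' `[maf_lo, maf_hi)` and it is not already a risk variant, assign it
#' `beta_j = log(or_c)`; stop after `n_risk` selections.  This samples risk
#' classes in proportion to the occupancy of each MAF range in the
#' population.  All other variants are neutral (`beta_j = 0`).
#'
#' @param pop a [haplotype_population()].
#' @param classes risk-class data frame from [risk_class()], or `NULL` for
#'   a null model with no risk variants.
#' @param n_risk number of risk variants (default 50; ignored for the null
#'   model).
#' @param f0 wild-type penetrance (default 0.05).
#' @param seed RNG seed.
#' @param max_draws cap on rejection draws, guarding mis-specified classes.
#' @return object of class `disease_model`: `beta0`, `beta` (per-variant
#'   log odds ratios), `risk_variants` (indices), `classes`, `f0`.
#' @export
assign_disease_model <- function(pop, classes = NULL, n_risk = 50L,
                                 f0 = 0.05, seed = NULL, max_draws = 1e6) {
  stopifnot(inherits(pop, "haplotype_population"), f0 > 0, f0 < 1)
  v <- ncol(pop$haplotypes)
  beta <- numeric(v)
  risk <- integer(0)
  if (!is.null(classes) && n_risk > 0L) {
    stopifnot(all(c("maf_lo", "maf_hi", "or") %in% names(classes)))
    maf <- pmin(pop$pop_allele_freq, 1 - pop$pop_allele_freq)
    class_of <- rep(NA_integer_, v)
    for (c_idx in seq_len(nrow(classes))) {
      inside <- maf >= classes$maf_lo[c_idx] & maf < classes$maf_hi[c_idx]
      class_of[inside & is.na(class_of)] <- c_idx
    }
    if (sum(!is.na(class_of)) < n_risk)
      stop("fewer than n_risk variants eligible for the risk classes")
    if (!is.null(seed)) {
      restore <- .with_seed(seed)
      on.exit(restore())
    }
    draws <- 0
    while (length(risk) < n_risk) {
      draws <- draws + 1
      if (draws > max_draws) stop("risk-variant selection exceeded max_draws")
      j <- sample.int(v, 1L)
      if (!is.na(class_of[j]) && beta[j] == 0) {
        beta[j] <- log(classes$or[class_of[j]])
        risk <- c(risk, j)
      }
    }
  }
  structure(list(beta0 = stats::qlogis(f0), beta = beta,
                 risk_variants = sort(risk), classes = classes, f0 = f0),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Logistic disease model: f0 =", x$f0, "(beta0 =",
      round(x$beta0, 4), ")\n")
  cat("  risk variants:", length(x$risk_variants), "\n")
  invisible(x)
}

#' Penetrance of multi-variant genotypes
#'
#' `P(A | G) = logistic(beta0 + sum_j beta_j G_j)` with `G_j` minor-allele
#' counts; each minor allele multiplies the disease odds by the variant's
#' odds ratio, independently across variants.
#'
#' @param g genotype vector (length = number of variants) or matrix
#'   (individuals x variants) of minor-allele counts.
#' @param model a `disease_model` from [assign_disease_model()].
#' @return penetrance value(s) in `(0, 1)`.
#' @export
penetrance <- function(g, model) {
  stopifnot(inherits(model, "disease_model"))
  if (is.matrix(g)) {
    stats::plogis(model$beta0 + as.vector(g %*% model$beta))
  } else {
    stats::plogis(model$beta0 + sum(g * model$beta))
  }
}
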