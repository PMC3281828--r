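#' Two-variant locus model: one rare neutral, one rare risk variant
#'
#' Both biallelic variants share MAF `p`; variant 1 is neutral and variant 2
#' carries the risk.  Haplotype frequencies over (variant 1, variant 2)
#' minor-allele indicators, for LD coefficient `D`, are
#' `h(0,0) = (1-p)^2 + D`, `h(0,1) = h(1,0) = (1-p) p - D`,
#' `h(1,1) = p^2 + D`, with `D` in `[-p^2, p (1-p)]` (equivalently LD
#' correlation \eqn{r = D / (p (1-p))} in `[-p/(1-p), 1]`).  The nine two-variant
#' genotype classes get population frequencies by random union of haplotypes
#' (HWE).  Penetrance is multiplicative in the risk-variant minor-allele
#' count: `P(A | G_k) = f0 * gamma^{G_2k}`, and the case/control conditional
#' class frequencies follow by Bayes' rule.
#'
#' @param p shared minor allele frequency, in `(0, 0.5]`.
#' @param D LD coefficient between the minor alleles.
#' @param gamma relative risk per minor allele at the risk variant.
#' @param f0 penetrance of the major-allele homozygote at the risk variant.
#' @return object of class `two_variant_model`: haplotype frequencies `h`,
#'   class table `classes` (columns `g1`, `g2`, `p_k`, `p_case`, `p_ctrl`,
#'   `penetrance`), disease prevalence `prev`, and the inputs.
#' @export
two_variant_model <- function(p, D, gamma, f0) {
  stopifnot(p > 0, p <= 0.5, gamma > 0, f0 > 0)
  eps <- 1e-12
  if (D < -p^2 - eps || D > p * (1 - p) + eps)
    stop("D must lie in [-p^2, p(1-p)]")
  if (f0 * gamma^2 > 1 + eps)
    stop("penetrance f0 * gamma^2 exceeds 1")
  h <- c(`00` = (1 - p)^2 + D, `01` = (1 - p) * p - D,
         `10` = (1 - p) * p - D, `11` = p^2 + D)
  h <- pmax(h, 0)  # guard exact-boundary negatives from rounding
  hap <- cbind(g1 = c(0, 0, 1, 1), g2 = c(0, 1, 0, 1))
  classes <- expand.grid(g1 = 0:2, g2 = 0:2)
  p_k <- numeric(9)
  for (a in 1:4) for (b in 1:4) {
    g1 <- hap[a, "g1"] + hap[b, "g1"]
    g2 <- hap[a, "g2"] + hap[b, "g2"]
    k <- which(classes$g1 == g1 & classes$g2 == g2)
    p_k[k] <- p_k[k] + h[a] * h[b]
  }
  pen <- f0 * gamma^classes$g2
  prev <- sum(p_k * pen)
  classes$p_k <- p_k
  classes$penetrance <- pen
  classes$p_case <- p_k * pen / prev
  classes$p_ctrl <- p_k * (1 - pen) / (1 - prev)
  structure(list(p = p, D = D, r = D / (p * (1 - p)), gamma = gamma,
                 f0 = f0, h = h, classes = classes, prev = prev),
            class = "two_variant_model")
}

#' @export
print.two_variant_model <- function(x, ...) {
  cat(sprintf(
    "Two-variant locus model: p = %g, D = %g (r = %.4g), gamma = %g, f0 = %g\n",
    x$p, x$D, x$r, x$gamma, x$f0))
  cat(sprintf("  disease prevalence: %.4g\n", x$prev))
  invisible(x)
}

# E[U], Var0(U), Var1(U) for arbitrary class scores X, case/control class
# frequencies pA/pC and case-control sample sizes R, S (N = R + S):
#   E[U]    = (R S / N)  * sum X (pA - pC)
#   Var0(U) = (R S / N)  * [sum X^2 pbar - (sum X pbar)^2],  pbar = (R pA + S pC)/N
#   Var1(U) = (R S / N^2) * [S varA(X) + R varC(X)]
.u_moments <- function(X, pA, pC, R, S) {
  N <- R + S
  pbar <- (R * pA + S * pC) / N
  EU <- (R * S / N) * sum(X * (pA - pC))
  var0 <- (R * S / N) * (sum(X^2 * pbar) - sum(X * pbar)^2)
  varA <- sum(X^2 * pA) - sum(X * pA)^2
  varC <- sum(X^2 * pC) - sum(X * pC)^2
  var1 <- (R * S / N^2) * (S * varA + R * varC)
  list(EU = EU, var0 = var0, var1 = var1)
}

#' Moments of the generalized score statistic under a two-variant model
#'
#' Expectation and variances of `U` under the null and the alternative for a
#' given score scheme and sample sizes; the finite-sample statistic from
#' [generalized_statistic()] is asymptotically normal with these moments.
#'
#' @param model a [two_variant_model()].
#' @param scheme a [score_scheme()] over the two variants, or a numeric
#'   vector of 9 per-class scores.
#' @param N total sample size.
#' @param case_fraction fraction of cases (`R = round(N * case_fraction)`).
#' @return list with `EU`, `var0`, `var1`, and `valid` (`FALSE` when the
#'   scores are constant over the class distribution, degenerate scheme).
#' @export
score_moments <- function(model, scheme, N, case_fraction = 0.5) {
  stopifnot(inherits(model, "two_variant_model"))
  cl <- model$classes
  X <- if (inherits(scheme, "score_scheme"))
    scheme_scores(scheme, as.matrix(cl[, c("g1", "g2")])) else scheme
  stopifnot(length(X) == 9L)
  R <- round(N * case_fraction); S <- N - R
  mom <- .u_moments(X, cl$p_case, cl$p_ctrl, R, S)
  mom$valid <- mom$var0 > 0 && mom$var1 > 0
  mom
}

#' Asymptotic power of a two-sided test based on the trend-type statistic
#'
#' Power of the level-`alpha` two-sided test that rejects when
#' `T = U^2 / Var0-hat >= qchisq(1 - alpha, 1)`, computed from the normal
#' approximation `U ~ N(E[U], Var1)` with the variance-ratio-adjusted
#' critical value:
#' `power = Phi((-z sqrt(Var0) - E[U]) / sqrt(Var1)) +
#'          1 - Phi((z sqrt(Var0) - E[U]) / sqrt(Var1))`, `z = z_{1-alpha/2}`.
#' The algebraically identical noncentral chi-square form -- critical value
#' `qchisq(1-alpha, 1) * Var0/Var1`, noncentrality `E[U]^2 / Var1` -- is also
#' evaluated, and the two are required to agree to `1e-10`.  Under the null
#' (`gamma = 1`) the power equals `alpha` exactly.
#'
#' @param model a [two_variant_model()].
#' @param scheme a [score_scheme()] or 9-vector of class scores.
#' @param N total sample size.
#' @param case_fraction fraction of cases.
#' @param alpha two-sided type I error level.
#' @return power in `[0, 1]`.
#' @export
asymptotic_power <- function(model, scheme, N, case_fraction = 0.5,
                             alpha = 0.05) {
  mom <- score_moments(model, scheme, N, case_fraction)
  if (!mom$valid) stop("degenerate score scheme: zero variance")
  .power_from_moments(mom$EU, mom$var0, mom$var1, alpha)
}

.power_from_moments <- function(EU, var0, var1, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  s0 <- sqrt(var0); s1 <- sqrt(var1)
  pow_normal <- stats::pnorm((-z * s0 - EU) / s1) +
    stats::pnorm((z * s0 - EU) / s1, lower.tail = FALSE)
  pow_chisq <- stats::pchisq(stats::qchisq(1 - alpha, df = 1) * var0 / var1,
                             df = 1, ncp = EU^2 / var1, lower.tail = FALSE)
  if (abs(pow_normal - pow_chisq) > 1e-10)
    stop("internal inconsistency between power formulations")
  pow_normal
}

#' Power of the single-variant trend test at the risk variant
#'
#' Level-`alpha` two-sided Cochran-Armitage trend power for the risk variant
#' alone, using its marginal three-class genotype distribution (which does
#' not depend on `D`).  With `alpha/2` this is the locus-wide power lower
#' bound for the Bonferroni-corrected maximum trend (BC-CA) test at a
#' two-variant locus: joint inference over correlated statistics is
#' intractable, but the BC-CA test rejects at least whenever the
#' Bonferroni-corrected single-variant test at the risk variant does.
#'
#' @param model a [two_variant_model()].
#' @param N total sample size.
#' @param case_fraction fraction of cases.
#' @param alpha the (possibly Bonferroni-adjusted) level.
#' @return power in `[0, 1]`.
#' @export
risk_variant_trend_power <- function(model, N, case_fraction = 0.5,
                                     alpha = 0.05) {
  cl <- model$classes
  g2 <- 0:2
  pA <- vapply(g2, function(g) sum(cl$p_case[cl$g2 == g]), numeric(1))
  pC <- vapply(g2, function(g) sum(cl$p_ctrl[cl$g2 == g]), numeric(1))
  R <- round(N * case_fraction); S <- N - R
  mom <- .u_moments(g2, pA, pC, R, S)
  .power_from_moments(mom$EU, mom$var0, mom$var1, alpha)
}

#' Analytic power curves over the attainable LD range
#'
#' Sweeps the LD coefficient over a grid of 101 equally spaced values of `D`
#' (100 increments) from `D_min = -p^2` to `D_max = p (1-p)` and reports the
#' locus-wide power of the collapsing test, the summing test, and the BC-CA
#' lower bound (the risk-variant trend test at level `alpha / 2`, constant in
#' `D` because it depends only on the risk-variant marginal).
#'
#' @param p shared MAF; `gamma` relative risk; `f0` baseline penetrance.
#' @param gamma,f0 disease-model parameters (see [two_variant_model()]).
#' @param N total sample size; `case_fraction` fraction of cases.
#' @param case_fraction fraction of cases.
#' @param alpha two-sided level.
#' @param n_grid number of grid points (101 = 100 increments).
#' @return data frame with columns `D`, `r`, `power_collapse`, `power_sum`,
#'   `power_bcca_lb`.
#' @export
power_curve <- function(p, gamma, f0, N, case_fraction = 0.5, alpha = 0.05,
                        n_grid = 101L) {
  D_grid <- seq(-p^2, p * (1 - p), length.out = n_grid)
  collapse <- score_scheme("collapse")
  summing <- score_scheme("sum")
  out <- data.frame(D = D_grid, r = D_grid / (p * (1 - p)),
                    power_collapse = NA_real_, power_sum = NA_real_,
                    power_bcca_lb = NA_real_)
  for (i in seq_len(n_grid)) {
    mod <- two_variant_model(p, D_grid[i], gamma, f0)
    out$power_collapse[i] <- asymptotic_power(mod, collapse, N, case_fraction, alpha)
    out$power_sum[i] <- asymptotic_power(mod, summing, N, case_fraction, alpha)
    out$power_bcca_lb[i] <-
      risk_variant_trend_power(mod, N, case_fraction, alpha / 2)
  }
  out
}
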