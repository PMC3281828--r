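#' Exact binomial summary of rejection counts
#'
#' Rejection rate with the Clopper-Pearson exact 95% confidence interval:
#' lower bound `qbeta(0.025, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(0.975, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of rejections.
#' @param n number of valid analyses.
#' @param conf confidence level (default 0.95).
#' @return list with `rate`, `lower`, `upper`, `x`, `n`.
#' @export
summarize_rejections <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- (1 - conf) / 2
  list(
    rate = x / n,
    lower = if (x == 0) 0 else stats::qbeta(a, x, n - x + 1),
    upper = if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x),
    x = x, n = n
  )
}

#' Configure a type I error / power study
#'
#' Bundles the simulation, disease-model, sampling and testing settings for
#' [run_study()].  The defaults reproduce the full-scale study design
#' (balanced samples, call rates 1 / 0.995 / 0.95, alpha 0.05 and 0.01,
#' 1,000 replicates, 10,000 permutations); desk-scale runs override
#' `replicates`, `m` and the coalescent scale.
#'
#' @param classes risk classes ([risk_class()] rows) or `NULL` for a null
#'   model.
#' @param n_risk number of risk variants per population.
#' @param f0 wild-type penetrance.
#' @param N total sample size (balanced unless `case_fraction` changes).
#' @param case_fraction fraction of cases.
#' @param call_rates per-base-pair call rates to mask at.
#' @param alpha nominal levels evaluated.
#' @param tests subset of `c("bcca", "camax", "casum", "cmc", "wss")`.
#' @param m permutations per permutation test.
#' @param replicates number of (population, sample) replicates.
#' @param pool_size number of pre-simulated populations reused round-robin
#'   across replicates, or `NULL` for a fresh population per replicate.
#' @param n_hap,locus_length_bp,mu,rho,Ne,backend coalescent settings (see
#'   [simulate_population()]).
#' @param seed master seed; all per-replicate randomness derives from it.
#' @return a `study_config` list.
#' @export
study_config <- function(classes = NULL, n_risk = 50L, f0 = 0.05,
                         N = 500L, case_fraction = 0.5,
                         call_rates = c(1, 0.995, 0.95),
                         alpha = c(0.05, 0.01),
                         tests = c("bcca", "camax", "casum", "cmc", "wss"),
                         m = 10000L, replicates = 1000L, pool_size = NULL,
                         n_hap = 10000L, locus_length_bp = 100000L,
                         mu = 2.5e-8, rho = 1e-8, Ne = 10000L,
                         backend = "internal", seed = 1L) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(replicates >= 1, all(call_rates > 0 & call_rates <= 1))
  structure(list(classes = classes, n_risk = n_risk, f0 = f0, N = N,
                 case_fraction = case_fraction, call_rates = call_rates,
                 alpha = alpha, tests = tests, m = m,
                 replicates = replicates, pool_size = pool_size,
                 n_hap = n_hap, locus_length_bp = locus_length_bp,
                 mu = mu, rho = rho, Ne = Ne, backend = backend,
                 seed = seed),
            class = "study_config")
}

#' Run a type I error / power study
#'
#' For each replicate: simulate (or reuse) a haplotype population, assign the
#' disease model (risk variants are selected once per population), draw a
#' balanced case-control sample, generate one masked dataset per call rate,
#' and apply every requested test.  A test rejects at level `alpha` when its
#' p-value is `<= alpha`.  Invalid results (e.g. CMC with effective
#' denominator df `<= 4`, or unperformable analyses) are excluded from the
#' rejection-rate estimates and counted separately.  Identical master seeds
#' give identical results.
#'
#' @param config a [study_config()].
#' @param progress print a line per replicate chunk.
#' @return object of class `rv_study`: `results` (one row per replicate x
#'   call rate x test: statistic, p, valid, reason) and `summary` (per test
#'   x call rate x alpha: valid count, rejections, rate, exact binomial 95%
#'   CI, invalid count).
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  restore <- .with_seed(config$seed)
  seeds <- matrix(sample.int(2^31 - 2L, 4L * config$replicates),
                  ncol = 4L)  # per-replicate: model, sample, mask, tests
  pool <- NULL
  if (!is.null(config$pool_size)) {
    pool_seeds <- sample.int(2^31 - 2L, config$pool_size)
    pool <- lapply(pool_seeds, function(s)
      simulate_population(config$n_hap, config$locus_length_bp, config$mu,
                          config$rho, config$Ne, backend = config$backend,
                          seed = s))
  }
  pop_seeds <- sample.int(2^31 - 2L, config$replicates)
  restore()
  R <- round(config$N * config$case_fraction)
  S <- config$N - R
  rows <- list()
  for (rep_i in seq_len(config$replicates)) {
    pop <- if (!is.null(pool)) pool[[(rep_i - 1L) %% length(pool) + 1L]]
           else simulate_population(config$n_hap, config$locus_length_bp,
                                    config$mu, config$rho, config$Ne,
                                    backend = config$backend,
                                    seed = pop_seeds[rep_i])
    model <- assign_disease_model(pop, config$classes, config$n_risk,
                                  config$f0, seed = seeds[rep_i, 1L])
    gd_full <- sample_case_control(pop, model, R, S, seed = seeds[rep_i, 2L])
    for (cr_i in seq_along(config$call_rates)) {
      cr <- config$call_rates[cr_i]
      gd <- apply_missingness(gd_full, cr,
                              seed = (seeds[rep_i, 3L] + cr_i) %% 2147483646 + 1)
      res <- .run_tests(gd, config$tests, config$m,
                        seed = (seeds[rep_i, 4L] + cr_i) %% 2147483646 + 1,
                        alpha_bcca = config$alpha)
      for (r in res) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, call_rate = cr, test = r$test,
          alpha = r$alpha, statistic = r$statistic, p = r$p,
          reject = r$reject, valid = r$valid, reason = r$reason,
          stringsAsFactors = FALSE)
      }
    }
    if (progress && rep_i %% 50L == 0L)
      message("replicate ", rep_i, "/", config$replicates)
  }
  results <- do.call(rbind, rows)
  summary <- .summarize_study(results, config$alpha)
  structure(list(results = results, summary = summary, config = config),
            class = "rv_study")
}

# Apply the requested tests to one dataset; BC-CA is a decision test so it
# is evaluated per alpha, the p-value tests once with rejection per alpha.
.run_tests <- function(gd, tests, m, seed, alpha_bcca) {
  out <- list()
  add_p <- function(test, statistic, p, valid = TRUE, reason = NA_character_) {
    for (a in alpha_bcca) {
      out[[length(out) + 1L]] <<- list(
        test = test, alpha = a, statistic = statistic, p = p,
        reject = if (valid && !is.na(p)) p <= a else NA,
        valid = valid, reason = reason)
    }
  }
  if (any(c("camax", "casum") %in% tests)) {
    which_sum <- intersect(c("max", "sum"),
                           sub("ca", "", intersect(tests, c("camax", "casum"))))
    res <- ca_perm_test(gd, summary = which_sum, m = m, seed = seed)
    if (inherits(res, "rv_test")) res <- stats::setNames(list(res), which_sum)
    for (s in names(res))
      add_p(paste0("ca", s), res[[s]]$statistic, res[[s]]$p.value,
            res[[s]]$valid, res[[s]]$reason)
  }
  if ("bcca" %in% tests) {
    scan <- trend_scan(gd)
    for (a in alpha_bcca) {
      r <- bcca_test(scan, alpha = a)
      out[[length(out) + 1L]] <- list(
        test = "bcca", alpha = a, statistic = r$statistic,
        p = r$p.value, reject = if (r$valid) r$reject else NA,
        valid = r$valid, reason = r$reason)
    }
  }
  if ("cmc" %in% tests) {
    r <- cmc_test(gd)
    add_p("cmc", r$statistic, r$p.value, r$valid, r$reason)
  }
  if ("wss" %in% tests) {
    r <- wss_test(gd, m = m, seed = (seed + 104729) %% 2147483646 + 1)
    add_p("wss", r$statistic, r$p.value, r$valid, r$reason)
  }
  out
}

.summarize_study <- function(results, alphas) {
  cells <- unique(results[, c("test", "call_rate", "alpha")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$test == cells$test[i] &
      results$call_rate == cells$call_rate[i] &
      results$alpha == cells$alpha[i]
    sub <- results[sel, ]
    valid <- sub[sub$valid & !is.na(sub$reject), ]
    n_valid <- nrow(valid)
    x <- sum(valid$reject)
    ci <- if (n_valid >= 1) summarize_rejections(x, n_valid)
          else list(rate = NA_real_, lower = NA_real_, upper = NA_real_)
    data.frame(test = cells$test[i], call_rate = cells$call_rate[i],
               alpha = cells$alpha[i], n_valid = n_valid, rejections = x,
               rate = ci$rate, ci_lower = ci$lower, ci_upper = ci$upper,
               n_invalid = nrow(sub) - n_valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.rv_study <- function(x, ...) {
  cat("Association-test study:", x$config$replicates, "replicates, N =",
      x$config$N, "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
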