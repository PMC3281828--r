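test_that("segregating sites match the Watterson expectation across sample sizes", {
  # E[S] = theta * sum 1/i; recombination-free, so exact for the internal
  # backend at any n
  theta <- 10
  mu <- theta / (4 * 10000 * 1000)  # theta = 4 Ne mu L with Ne = 1e4, L = 1e3
  for (cfg in list(list(n = 2, reps = 400), list(n = 10, reps = 200),
                   list(n = 100, reps = 100))) {
    S <- vapply(seq_len(cfg$reps), function(i) {
      ncol(simulate_population(cfg$n, 1000, mu = mu, Ne = 10000,
                               seed = 7000 + i)$haplotypes)
    }, numeric(1))
    ES <- expected_segsites(cfg$n, 1000, mu = mu, Ne = 10000)
    se <- stats::sd(S) / sqrt(cfg$reps)
    expect_lt(abs(mean(S) - ES), 3 * se + 1e-9)
  }
})

test_that("simulated populations have sorted unit-interval positions, all polymorphic", {
  pop <- simulate_population(50, 5000, mu = 1e-6, Ne = 10000, seed = 5)
  expect_true(all(pop$positions > 0 & pop$positions < 1))
  expect_false(is.unsorted(pop$positions))
  f <- colMeans(pop$haplotypes)
  expect_true(all(f > 0 & f < 1))
})

test_that("the msprime adapter produces a valid population with plausible S", {
  pop <- simulate_population(30, 20000, mu = 2.5e-8, rho = 1e-8, Ne = 10000,
                             backend = "msprime", seed = 11)
  expect_s3_class(pop, "haplotype_population")
  expect_equal(nrow(pop$haplotypes), 30)
  ES <- expected_segsites(30, 20000)   # = 20 * H_29 ~ 79
  expect_gt(ncol(pop$haplotypes), ES / 3)
  expect_lt(ncol(pop$haplotypes), ES * 3)
})

test_that("risk-variant selection respects class intervals and counts", {
  pop <- simulate_population(500, 20000, mu = 5e-7, Ne = 10000, seed = 13)
  classes <- rbind(risk_class(0, 0.05, 3))
  model <- assign_disease_model(pop, classes, n_risk = 10, seed = 17)
  expect_length(model$risk_variants, 10)
  maf <- minor_alleles(pop)$maf
  expect_true(all(maf[model$risk_variants] < 0.05))
  expect_true(all(model$beta[model$risk_variants] == log(3)))
  expect_true(all(model$beta[-model$risk_variants] == 0))
  # null model: no risk variants
  null_model <- assign_disease_model(pop, NULL)
  expect_true(all(null_model$beta == 0))
})

test_that("risk classes are sampled in proportion to their MAF-range occupancy", {
  pop <- simulate_population(500, 50000, mu = 5e-7, Ne = 10000, seed = 19)
  maf <- minor_alleles(pop)$maf
  classes <- rbind(risk_class(0, 0.01, 2), risk_class(0.01, 0.05, 1.5),
                   risk_class(0.05, 0.5, 1.2))
  eligible <- c(sum(maf < 0.01), sum(maf >= 0.01 & maf < 0.05),
                sum(maf >= 0.05))
  counts <- c(0, 0, 0)
  for (s in 1:40) {
    model <- assign_disease_model(pop, classes, n_risk = 20, seed = s)
    b <- model$beta[model$risk_variants]
    counts <- counts + c(sum(b == log(2)), sum(b == log(1.5)),
                         sum(b == log(1.2)))
  }
  gof <- stats::chisq.test(counts, p = eligible / sum(eligible))
  expect_gt(gof$p.value, 0.001)
})

test_that("penetrance follows the logistic odds model", {
  pop <- random_pop(100, 10, seed = 23)
  model <- assign_disease_model(pop, rbind(risk_class(0, 0.51, 3)),
                                n_risk = 1, f0 = 0.05, seed = 29)
  j <- model$risk_variants
  g0 <- integer(10)
  expect_equal(penetrance(g0, model), 0.05)
  g1 <- g0; g1[j] <- 1L
  expect_equal(penetrance(g1, model), 0.0526316 * 3 / (1 + 0.0526316 * 3),
               tolerance = 1e-5)
  expect_equal(penetrance(g1, model), 0.136364, tolerance = 1e-5)
  g2 <- g0; g2[j] <- 2L
  expect_equal(penetrance(g2, model), 0.321429, tolerance = 1e-5)
  # multiplicative on the odds scale
  odds <- function(p) p / (1 - p)
  expect_equal(odds(penetrance(g2, model)) / odds(penetrance(g1, model)),
               odds(penetrance(g1, model)) / odds(penetrance(g0, model)),
               tolerance = 1e-10)
})

test_that("case-control sampling returns exactly R cases and S controls", {
  pop <- simulate_population(400, 10000, seed = 31)
  model <- assign_disease_model(pop, rbind(risk_class(0, 0.01, 3)),
                                n_risk = 5, seed = 37)
  gd <- sample_case_control(pop, model, R = 30, S = 45, seed = 41)
  expect_equal(gd$R, 30)
  expect_equal(gd$S, 45)
  expect_equal(gd$case, c(rep(1L, 30), rep(0L, 45)))
  expect_equal(ncol(gd$genotypes), ncol(pop$haplotypes))
})

test_that("under a null model sample allele frequencies track the population", {
  pop <- simulate_population(2000, 10000, mu = 2.5e-7, seed = 43)
  model <- assign_disease_model(pop, NULL)
  gd <- sample_case_control(pop, model, R = 400, S = 400, seed = 47)
  maf_pop <- minor_alleles(pop)$maf
  common <- which(maf_pop > 0.1)
  f_sample <- colMeans(gd$genotypes[, common, drop = FALSE]) / 2
  se <- sqrt(maf_pop[common] * (1 - maf_pop[common]) / (2 * 800))
  expect_true(all(abs(f_sample - maf_pop[common]) < 4 * se))
})

test_that("call rate 1 leaves genotypes untouched", {
  pop <- simulate_population(200, 5000, seed = 53)
  gd <- sample_cohort(pop, 50, seed = 59)
  expect_identical(apply_missingness(gd, 1), gd)
})

test_that("the Markov-chain mask hits the expected observed fraction", {
  pop <- simulate_population(200, 100000, mu = 2.5e-8, seed = 61)
  gd <- sample_cohort(pop, 500, seed = 67)
  masked <- apply_missingness(gd, 0.95, seed = 71)
  obs_frac <- mean(!is.na(masked$genotypes))
  # binomial SE understates the clustered process; use a loose band
  expect_lt(abs(obs_frac - 0.95), 0.02)
  expect_gt(sum(is.na(masked$genotypes)), 0)
})

test_that("missingness is independent of case status", {
  pop <- simulate_population(300, 50000, mu = 5e-8, seed = 73)
  model <- assign_disease_model(pop, NULL)
  gd <- sample_case_control(pop, model, 100, 100, seed = 79)
  masked <- apply_missingness(gd, 0.9, seed = 83)
  miss_by_ind <- rowSums(is.na(masked$genotypes))
  p <- stats::wilcox.test(miss_by_ind ~ masked$case)$p.value
  expect_gt(p, 0.001)
})
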