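# two-group toy data with 2 common variants, no rare variants
hotelling_gd <- function() {
  G <- rbind(
    matrix(c(2, 1, 1, 1, 2, 2, 1, 0, 2, 1, 1, 2, 2, 2, 0, 1, 1, 1, 2, 0), 10),
    matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1, 1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 1), 10)
  )
  storage.mode(G) <- "integer"
  make_gd(G, rep(c(1, 0), each = 10))
}

# textbook two-sample Hotelling's T2 with a standard inverse
hotelling_oracle <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- colMeans(X1) - colMeans(X2)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp) %*% d)
}

test_that("identical genotype composition in both groups gives T2 = 0, p = 1", {
  block <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L,
                    1L, 0L, 1L, 2L, 0L, 1L), ncol = 2)
  gd <- make_gd(rbind(block, block), rep(c(1, 0), each = 6))
  res <- cmc_test(gd)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("full-rank data matches the textbook two-sample Hotelling T2", {
  gd <- hotelling_gd()
  res <- cmc_test(gd)
  X <- gd$genotypes
  T2 <- hotelling_oracle(X[1:10, ], X[11:20, ])
  expect_equal(res$statistic, T2, tolerance = 1e-10)
  expect_equal(res$v_effective, 2L)
  expect_equal(res$ddf, 20 - 2 - 1)
  # F approximation
  expect_equal(res$F, (17 / (18 * 2)) * T2, tolerance = 1e-10)
  expect_equal(res$p.value, stats::pf(res$F, 2, 17, lower.tail = FALSE))
  expect_true(res$valid)
})

test_that("duplicating a common-variant column leaves T2 and p unchanged", {
  gd <- hotelling_gd()
  base <- cmc_test(gd)
  gd_dup <- make_gd(cbind(gd$genotypes, gd$genotypes[, 2]), gd$case)
  dup <- cmc_test(gd_dup)
  expect_equal(dup$statistic, base$statistic, tolerance = 1e-8)
  expect_equal(dup$v_effective, base$v_effective)  # rank unchanged
  expect_equal(dup$p.value, base$p.value, tolerance = 1e-8)
  # column reordering is also immaterial
  gd_perm <- make_gd(gd$genotypes[, c(2, 1)], gd$case)
  expect_equal(cmc_test(gd_perm)$statistic, base$statistic, tolerance = 1e-10)
})

test_that("exclusion rules: missing common genotypes and ambiguous rare indicators", {
  # variant 1 common (MAF ~0.3), variants 2-3 rare (one carrier each)
  G <- rbind(
    c(1L, 1L, NA),   # rare minor observed -> usable despite missing rare
    c(NA, 0L, 0L),   # missing common -> excluded
    c(1L, NA, 0L),   # no observed rare minor + missing rare -> ambiguous
    c(0L, 0L, 0L),   # complete, indicator 0 -> usable
    c(2L, 0L, 0L),
    c(1L, 0L, 1L),
    c(0L, 0L, 0L),
    c(1L, 0L, 0L)
  )
  gd <- make_gd(G, c(1, 1, 1, 1, 0, 0, 0, 0))
  cv <- cmc_vector(gd, rare_maf = 0.2)
  expect_equal(cv$n_excluded_common, 1)
  expect_equal(cv$n_excluded_ambiguous, 1)
  expect_equal(sum(cv$usable), 6)
  expect_equal(unname(cv$X[, "rare_indicator"]), c(1, 0, 0, 1, 0, 0))
})

test_that("all individuals excluded yields an invalid 'no complete data' result", {
  # two common variants, every individual missing at least one of them
  G <- cbind(c(NA, 1L, NA, 1L), c(0L, NA, 1L, NA))
  gd <- make_gd(G, c(1, 1, 0, 0))
  res <- cmc_test(gd, rare_maf = 0.01)
  expect_false(res$valid)
  expect_match(res$reason, "no complete data")
})

test_that("small effective ddf flags the F test invalid", {
  set.seed(47)
  G <- matrix(sample(0:2, 14, replace = TRUE), ncol = 2)
  gd <- make_gd(G, c(1, 1, 1, 0, 0, 0, 0))
  res <- cmc_test(gd)
  expect_false(res$valid)  # ddf = 7 - v - 1 <= 4
})
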