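# WSS components computed by hand from their definitions, independent of
# the package implementation.
wss_oracle <- function(G, y, weight_n = "all") {
  v <- ncol(G)
  inv_w <- numeric(v)
  for (j in seq_len(v)) {
    obs <- !is.na(G[, j])
    ctrl_obs <- obs & y == 0
    q <- (sum(G[ctrl_obs, j]) + 1) / (2 * sum(ctrl_obs) + 2)
    n_w <- if (weight_n == "all") sum(obs) else sum(ctrl_obs)
    inv_w[j] <- 1 / sqrt(n_w * q * (1 - q))
  }
  G0 <- G; G0[is.na(G0)] <- 0
  scores <- as.vector(G0 %*% inv_w)
  sum(rank(scores)[y == 1])
}

test_that("control-based frequency estimate and weight match hand arithmetic", {
  # 4 controls observed with zero minor alleles -> q = 1/10; 10 observed
  # individuals -> w = sqrt(10 * 0.1 * 0.9)
  G <- cbind(c(1L, 0L, 2L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, NA, NA))
  y <- c(rep(1, 6), rep(0, 6))
  gd <- make_gd(G, y)
  # scores under the hand-computed weight
  w <- sqrt(10 * 0.1 * 0.9)
  expect_equal(w, 0.9487, tolerance = 1e-4)
  W_hand <- wss_oracle(gd$genotypes, y)
  res <- wss_test(gd, m = 19, seed = 1)
  expect_equal(res$statistic, W_hand)
})

test_that("an individual with all genotypes missing scores 0 and gets the shared midrank", {
  G <- cbind(c(2L, 1L, NA, 0L, 0L, 0L),
             c(1L, 0L, NA, 0L, 0L, 1L))
  y <- c(1, 1, 1, 0, 0, 0)
  gd <- make_gd(G, y)
  G0 <- gd$genotypes; G0[is.na(G0)] <- 0L
  # individual 3 ties with individual 5 (both all-zero scores)
  res <- wss_test(gd, m = 19, seed = 2)
  expect_equal(res$statistic, wss_oracle(gd$genotypes, y))
})

test_that("Monte Carlo two-sided p agrees with the exhaustive permutation value", {
  G <- cbind(c(2L, 1L, 1L, 0L, 0L, 0L),
             c(1L, 2L, 0L, 1L, 0L, 0L))
  y <- c(1, 1, 1, 0, 0, 0)
  gd <- make_gd(G, y)
  W_all <- exhaustive_perm(6, 3, function(yy) wss_oracle(G, yy))
  W_obs <- wss_oracle(G, y)
  W_bar <- mean(W_all)
  p_exact <- mean(abs(W_all - W_bar) >= abs(W_obs - W_bar) - 1e-12)
  res <- wss_test(gd, m = 10000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  # the Monte Carlo W_bar differs from the exhaustive mean; allow both noise
  # sources
  expect_lt(abs(res$p.value - p_exact), 3 * se + 0.02)
})

test_that("weights are recomputed per permutation by default, freezable by flag", {
  set.seed(53)
  G <- matrix(sample(c(0L, 0L, 0L, 1L, 2L), 60, replace = TRUE), ncol = 4)
  gd <- make_gd(G, rep(c(1, 0), length.out = 15))
  a <- wss_test(gd, m = 200, seed = 11, keep_null = TRUE)
  b <- wss_test(gd, m = 200, seed = 11, recompute_weights = FALSE,
                keep_null = TRUE)
  expect_identical(a$statistic, b$statistic)  # observed W unaffected
  expect_false(identical(a$null, b$null))     # permutation nulls differ
})

test_that("two-sided p-values are symmetric under label mirroring", {
  set.seed(59)
  G <- matrix(sample(c(0L, 0L, 1L, 2L), 48, replace = TRUE), ncol = 4)
  y <- rep(c(1, 0), 6)
  gd <- make_gd(G, y)
  gd_flip <- make_gd(G, 1 - y)
  a <- wss_test(gd, m = 2000, seed = 13)
  b <- wss_test(gd_flip, m = 2000, seed = 13)
  # balanced design: flipping labels reflects W about its permutation mean,
  # so the two-sided p-values agree up to Monte Carlo noise
  expect_lt(abs(a$p.value - b$p.value), 0.05)
})

test_that("WSS p-values are super-uniform under the null", {
  set.seed(61)
  n_rep <- 400
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    G <- matrix(sample(0:2, 30 * 5, replace = TRUE, prob = c(.6, .3, .1)), 30)
    y <- sample(rep(c(1, 0), each = 15))
    rej[i] <- wss_test(make_gd(G, y), m = 99, seed = i)$p.value <= 0.05
  }
  ci <- summarize_rejections(sum(rej), n_rep)
  expect_lte(ci$lower, 0.05)
  expect_gte(ci$upper, 0.05)
})
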