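# draw a finite-sample case-control dataset from a two-variant model via
# multinomial class counts and evaluate the asymptotic-test decision
simulate_rejections <- function(mod, scores, N, alpha, n_rep, seed) {
  set.seed(seed)
  R <- N / 2; S <- N - R
  crit <- qchisq(1 - alpha, df = 1)
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    r_k <- as.vector(rmultinom(1, R, mod$classes$p_case))
    s_k <- as.vector(rmultinom(1, S, mod$classes$p_ctrl))
    st <- generalized_statistic(r_k, s_k, scores)
    rej[i] <- st$valid && st$T >= crit
  }
  mean(rej)
}

test_that("moments vanish appropriately under the null", {
  mod <- two_variant_model(0.01, 0.00005, gamma = 1, f0 = 0.05)
  mom <- score_moments(mod, score_scheme("sum"), N = 1000)
  expect_equal(mom$EU, 0)
  expect_equal(mom$var0, mom$var1, tolerance = 1e-12)
})

test_that("collapse-scheme E[U] equals the carrier-probability difference times RS/N", {
  p <- 0.01
  mod <- two_variant_model(p, D = -p^2, gamma = 3, f0 = 0.05)
  mom <- score_moments(mod, score_scheme("collapse"), N = 1000)
  cl <- mod$classes
  carrier <- cl$g1 + cl$g2 > 0
  diff <- sum(cl$p_case[carrier]) - sum(cl$p_ctrl[carrier])
  expect_equal(mom$EU, (500 * 500 / 1000) * diff, tolerance = 1e-12)
})

test_that("sample moments of U converge to the analytic formulas", {
  mod <- two_variant_model(0.02, 0.0001, gamma = 2, f0 = 0.05)
  scores <- scheme_scores(score_scheme("sum"),
                          as.matrix(mod$classes[, c("g1", "g2")]))
  N <- 1000; R <- 500; S <- 500
  mom <- score_moments(mod, scores, N)
  set.seed(71)
  n_rep <- 4000
  U <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    r_k <- as.vector(rmultinom(1, R, mod$classes$p_case))
    s_k <- as.vector(rmultinom(1, S, mod$classes$p_ctrl))
    U[i] <- generalized_statistic(r_k, s_k, scores)$U
  }
  expect_lt(abs(mean(U) - mom$EU), 3 * sd(U) / sqrt(n_rep))
  # variance of U under the alternative, within a generous MC band
  expect_lt(abs(var(U) - mom$var1) / mom$var1, 0.15)
})

test_that("power equals alpha under the null to 1e-10", {
  for (alpha in c(0.05, 0.01)) {
    mod <- two_variant_model(0.005, 0, gamma = 1, f0 = 0.05)
    for (scheme in list(score_scheme("collapse"), score_scheme("sum"),
                        score_scheme("trend", 2))) {
      expect_equal(asymptotic_power(mod, scheme, 1000, alpha = alpha), alpha,
                   tolerance = 1e-10)
    }
    expect_equal(risk_variant_trend_power(mod, 1000, alpha = alpha), alpha,
                 tolerance = 1e-10)
  }
})

test_that("power is non-decreasing in sample size", {
  mod <- two_variant_model(0.01, 0.00005, gamma = 2, f0 = 0.05)
  pows <- vapply(c(250, 500, 1000, 2000, 4000), function(N)
    asymptotic_power(mod, score_scheme("sum"), N), numeric(1))
  expect_true(all(diff(pows) >= -1e-12))
})

test_that("analytic power matches Monte Carlo rejection rates", {
  cases <- list(
    list(p = 0.005, D = 0, gamma = 3, f0 = 0.05, N = 1000, scheme = "sum"),
    list(p = 0.005, D = -0.005^2, gamma = 3, f0 = 0.05, N = 1000,
         scheme = "collapse"),
    list(p = 0.01, D = 0.00005, gamma = 2, f0 = 0.05, N = 2000,
         scheme = "sum"),
    list(p = 0.01, D = 0, gamma = 2, f0 = 0.05, N = 500, scheme = "collapse"),
    list(p = 0.02, D = 0.0001, gamma = 1.5, f0 = 0.1, N = 2000,
         scheme = "trend")
  )
  n_rep <- 4000
  for (cs in cases) {
    mod <- two_variant_model(cs$p, cs$D, cs$gamma, cs$f0)
    scheme <- if (cs$scheme == "trend") score_scheme("trend", 2)
              else score_scheme(cs$scheme)
    scores <- scheme_scores(scheme, as.matrix(mod$classes[, c("g1", "g2")]))
    pow <- asymptotic_power(mod, scheme, cs$N, alpha = 0.05)
    emp <- simulate_rejections(mod, scores, cs$N, 0.05, n_rep,
                               seed = 1000 + round(1e4 * cs$p))
    se <- sqrt(max(pow * (1 - pow), emp * (1 - emp)) / n_rep)
    expect_lt(abs(emp - pow), 3 * se + 0.005)
  }
})

test_that("at r = 1 the pooled tests reduce to single-variant trend tests", {
  p <- 0.005; gamma <- 3; f0 <- 0.05
  mod <- two_variant_model(p, D = p * (1 - p), gamma, f0)
  # dominant-score trend at the risk variant = collapse power
  cl <- mod$classes
  dom_power <- asymptotic_power(mod, as.numeric(cl$g2 > 0), 500)
  expect_equal(asymptotic_power(mod, score_scheme("collapse"), 500), dom_power,
               tolerance = 1e-10)
  # summing doubles the additive scores, and the statistic is scale-invariant
  add_power <- asymptotic_power(mod, cl$g2, 500)
  expect_equal(asymptotic_power(mod, score_scheme("sum"), 500), add_power,
               tolerance = 1e-10)
})

test_that("power_curve sweeps the attainable D range with a flat BC-CA bound", {
  pc <- power_curve(0.005, 3, 0.05, N = 500)
  expect_equal(nrow(pc), 101)
  expect_equal(pc$D[1], -0.005^2)
  expect_equal(pc$D[101], 0.005 * 0.995)
  expect_equal(pc$r[101], 1)
  expect_equal(diff(range(pc$power_bcca_lb)), 0, tolerance = 1e-12)
})

test_that("the BC-CA lower bound beats pooling for all r <= 0.08 in both models", {
  # rare-variant pair models: (MAF 0.005, RR 3) and (MAF 0.01, RR 2), N = 500
  for (cfg in list(c(0.005, 3), c(0.01, 2))) {
    pc <- power_curve(cfg[1], cfg[2], 0.05, N = 500, alpha = 0.05)
    low <- pc$r <= 0.08
    expect_true(all(pc$power_bcca_lb[low] > pc$power_collapse[low]))
    expect_true(all(pc$power_bcca_lb[low] > pc$power_sum[low]))
    # pooling does overtake the bound at larger positive correlations
    cross <- pc$r[pc$power_collapse > pc$power_bcca_lb |
                    pc$power_sum > pc$power_bcca_lb]
    expect_true(length(cross) > 0)
  }
})
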