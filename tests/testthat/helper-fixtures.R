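# Small in-code fixtures and independent oracles shared across test files.

# population with given haplotype rows (0/1 matrix), evenly spaced positions
make_pop <- function(H, L = 1000L) {
  H <- as.matrix(H)
  v <- ncol(H)
  haplotype_population(H, seq_len(v) / (v + 1), L)
}

# random polymorphic population: n haplotypes, v variants
random_pop <- function(n, v, seed, L = 1000L) {
  set.seed(seed)
  H <- matrix(0L, n, v)
  for (j in seq_len(v)) {
    k <- sample(seq_len(n - 1L), 1L)
    H[sample.int(n, k), j] <- 1L
  }
  make_pop(H, L)
}

# small genotype dataset from explicit matrix and labels
make_gd <- function(G, case, positions = NULL, L = 1000L) {
  v <- ncol(as.matrix(G))
  meta <- if (is.null(positions)) NULL else
    data.frame(id = paste0("v", seq_len(v)), position = positions)
  genotype_dataset(as.matrix(G), case, meta, L)
}

# Cochran-Armitage trend chi-square computed the textbook way from a 2x3
# table (cases r0,r1,r2; controls s0,s1,s2), scores 0/1/2 -- independent of
# the package's generalized-statistic path.
ca_trend_textbook <- function(r, s, scores = c(0, 1, 2)) {
  n <- r + s
  N <- sum(n); R <- sum(r)
  pbar <- R / N
  num <- sum(scores * (r - pbar * n))^2
  den <- pbar * (1 - pbar) * (sum(scores^2 * n) - sum(scores * n)^2 / N)
  num / den
}

# N * rho^2 from individual-level (genotype, label) pairs
n_rho2 <- function(g, y) {
  length(g) * stats::cor(g, y)^2
}

# exhaustive permutation distribution of a statistic over all case-label
# assignments of R cases among N individuals; stat_fun(labels) -> scalar
exhaustive_perm <- function(N, R, stat_fun) {
  combos <- utils::combn(N, R)
  apply(combos, 2L, function(idx) {
    y <- integer(N); y[idx] <- 1L
    stat_fun(y)
  })
}

# per-variant trend T values computed naively (loop + cor), NA-aware
naive_trend_T <- function(G, y) {
  vapply(seq_len(ncol(G)), function(j) {
    obs <- !is.na(G[, j])
    g <- G[obs, j]; yy <- y[obs]
    if (length(unique(g)) < 2 || length(unique(yy)) < 2) return(NA_real_)
    length(g) * stats::cor(g, yy)^2
  }, numeric(1))
}
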