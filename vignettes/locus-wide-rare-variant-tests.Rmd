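---
title: "Locus-wide association testing with rare variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-wide association testing with rare variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvlocus)
```

## The testing problem

A locus is a contiguous stretch of sequence containing many biallelic
variants, most of them rare (minor allele frequency, MAF, below 1%). Given
a case-control sample genotyped across the locus, we want a single
locus-wide test of association. Burden-style *pooling* tests reduce the
locus to one score per individual — either an indicator of carrying any
minor allele (*collapsing*) or a weighted count of minor alleles
(*summing*) — and compare it between groups. Pooling is attractive when
every pooled variant raises risk, but sequence data contain mostly neutral
variants, and pairwise linkage disequilibrium (LD) between rare variants is
predominantly *negative*: two variants of MAF `p` can be correlated no more
negatively than `r = -p/(1-p)` (−0.0101 at `p = 0.01`), yet most observed
pairs sit at or near that bound. Negative LD means minor alleles at neutral
variants preferentially sit on haplotypes *without* the risk allele, so
neutral-variant differences accumulate in controls and *mask* the
risk-variant signal inside a pooled score.

Tests built from nonnegative per-variant statistics do not mask: each
variant contributes the squared magnitude of its deviation regardless of
direction. This package implements both families so they can be compared
on equal terms:

* **BC-CA** — reject when the maximum single-variant Cochran–Armitage
  trend chi-square reaches the Bonferroni-corrected quantile
  `qchisq(1 - alpha/v, 1)`, `v` the number of polymorphic variants
  (`bcca_test()`).
* **CA max / CA sum** — permutation tests on the maximum or the sum of the
  per-variant trend chi-squares (`ca_perm_test()`). These are efficient:
  the permutation null absorbs the LD-induced correlation between
  statistics that makes Bonferroni conservative.
* **CMC** — rare variants (pooled-sample MAF ≤ 0.01) collapsed into an
  indicator, joined with common-variant counts, compared by two-sample
  Hotelling's T² with a g2 generalized inverse (`cmc_test()`).
* **WSS** — rank-sum test on sums of minor-allele counts weighted
  inversely by a control-based frequency estimate (`wss_test()`).

## The generalized trend statistic

All single-variant machinery flows from one statistic. For genotype
classes `k` with case counts `r_k`, control counts `s_k`, class totals
`n_k`, scores `X_k`, and `R`, `S`, `N = R + S`:

$$U = \frac{1}{N}\sum_k X_k (S\,r_k - R\,s_k), \qquad
\widehat{\mathrm{Var}}_0(U) = \frac{RS}{N^3}\Big[N\sum_k X_k^2 n_k -
\big(\textstyle\sum_k X_k n_k\big)^2\Big], \qquad
T = U^2/\widehat{\mathrm{Var}}_0(U).$$

With additive scores 0/1/2 at a single variant, `T` is the classical
Cochran–Armitage trend chi-square and equals `N * rho^2`, with `rho` the
genotype/label Pearson correlation — the form `trend_scan()` exploits.
Scores `I(any minor allele)` give the collapsing test and
`sum_j G_jk` the summing test, which is why one set of moment formulas
(below) covers all three. The SKAT statistic without covariates is a
weighted sum of squared per-variant score statistics
(`skat_statistic()`); with inverse-null-variance weights it *equals* the
sum of trend chi-squares on every dataset, including under missingness,
and with unit weights it is the C-alpha form. The CA sum test therefore
doubles as a permutation SKAT.

Missing genotypes: each variant's `T` uses only individuals observed at
that variant, and variants monomorphic among observed genotypes are
excluded. Permutation shuffles case labels over individuals while each
row's genotypes and missingness pattern stay fixed; that is exactly the
exchangeability that holds when genotypes are missing completely at random
(MCAR). The per-variant denominators and the exclusion set are
label-invariant, so they are precomputed once and each permutation reduces
to two matrix products — permutations are evaluated in blocks against a
label matrix for BLAS efficiency.

The permutation p-value is the add-one estimator
`p = (#{Q_t >= Q_obs} + 1)/(m + 1)` with ties counted toward the tail, so
`p >= 1/(m+1)` and the test is valid (never anticonservative) at any `m`.
When both CA max and CA sum are requested, one shared stream of shuffles
evaluates both; each p-value uses only its own statistic's null, so
sharing changes nothing statistically and halves the work.

## Pooling tests

**CMC.** The rare/common split uses pooled-sample MAF over observed
genotypes at a threshold of 0.01 (a flag). Individuals are unusable when
(a) any common-variant genotype is missing, or (b) no minor allele is
observed at any rare variant while at least one rare genotype is missing —
the indicator would then depend on unobserved data. LD among common
variants can make the pooled within-group covariance singular, so the
statistic uses a g2 (reflexive) generalized inverse computed by sweeping
each column in succession (`g2_sweep_inverse()`); a pivot below `1e-8`
times the largest original diagonal element marks a linearly dependent
column, whose row and column are zeroed. Any generalized inverse yields
the same T² as a standard inverse on a full-rank subset, so the effective
dimension `v` is the sweep rank, and the p-value uses the
`F(v, n - v - 1)` approximation with the classical pooled covariance
(denominator `n - 2`). Results with denominator df `n - v - 1 <= 4` are
flagged invalid: near rank deficiency, algebraically identical generalized
inverses can differ numerically, and the F distribution has no variance at
df ≤ 4.

**WSS.** Control-based frequency estimate
`q_j = (m_j^U + 1)/(2 n_j^U + 2)` over controls observed at variant `j`;
weight `w_j = sqrt(n_j q_j (1 - q_j))`; individual score
`sum_j G_ij / w_j` over observed genotypes (missing contributes 0, which
equals summing over non-missing genotypes only); `W` = sum of case
midranks. The p-value is two-sided — `|W - W̄|` against the permutation
distribution, `W̄` the mean over the same `m` permutations — because either
group may carry the minor-allele excess. Two points were genuinely open:
whether weights are recomputed inside each permutation, and whether `n_j`
counts all individuals or controls only. We recompute weights per
permutation (controls change under shuffling, and the original procedure
derives weights from the current controls) and count all individuals
observed at `j`; both choices are exposed as flags
(`recompute_weights`, `weight_n`).

## The two-variant analytic power model

One rare neutral variant and one rare risk variant share MAF `p`;
haplotype frequencies over minor-allele indicators are
`(1-p)^2 + D`, `(1-p)p - D` (twice), `p^2 + D`, with
`D ∈ [-p^2, p(1-p)]` and `r = D/(p(1-p))`. Genotype classes form by random
union of haplotypes (HWE), penetrance is multiplicative,
`P(A|G) = f0 * gamma^{G_2}`, and case/control class frequencies follow by
Bayes' rule (`two_variant_model()`). For any score scheme the moments of
`U` under null and alternative have closed forms (`score_moments()`), and
two-sided asymptotic power follows from the normal approximation with the
variance-ratio-corrected critical value; the algebraically identical
noncentral-chi-square form (noncentrality `E[U]^2/Var_1`) is computed too
and the two are asserted to agree to `1e-10`. At `gamma = 1` power equals
`alpha` exactly.

`power_curve()` sweeps `D` over 101 equally spaced points (100 increments)
including both endpoints — the boundary populations with a haplotype
frequency of exactly zero are valid. The BC-CA locus-wide power under LD
is intractable exactly, so the curve reports its lower bound: the
risk-variant-only trend test at level `alpha/2`, which is flat in `D`
because it depends only on the risk-variant marginal. The qualitative
result this machinery reproduces: at `N = 500`, `alpha = 0.05`, for both
rare-pair settings `(p, gamma) = (0.005, 3)` and `(0.01, 2)`, the BC-CA
lower bound exceeds collapsing and summing power everywhere `r <= 0.08` —
and essentially all observed rare-pair `r` values are negative.

## The simulation engine

`simulate_population()` generates haplotype populations under the standard
neutral coalescent with `theta = 4 Ne mu L`; the defaults (10,000
haplotypes, `L` = 100 kb, `mu = 2.5e-8`, `rho = 1e-8`, `Ne` = 10,000) give
`E[S] = theta * sum_{i<n} 1/i ≈ 978.8` expected segregating sites and a
rare-dominated MAF spectrum. Two backends: an internal, pure-R Hudson
coalescent without recombination (exponential coalescence times, Poisson
mutations on branches, uniform positions), and an adapter that runs
msprime through the system `python` with recombination and parses its
ms-format output. Recombination leaves `E[S]` unchanged but shrinks its
replicate variance and shapes LD, so LD-sensitive work should prefer the
msprime backend; the internal backend is the package default because it is
hermetic and exact in expectation. Replicate-to-replicate spread in the
segregating-site count is accordingly wider for the no-recombination
backend, which is why calibration checks compare means, not ranges.

Disease models are logistic in minor-allele counts,
`P(A|G) = logistic(beta0 + sum_j beta_j G_j)` with `beta0 = logit(f0)`,
`f0 = 0.05` by default. Risk variants (default 50, about 5% of variants in
an average population) are selected by uniform draws accepted when the
population MAF falls in a half-open class interval — e.g.
`[0, 0.005) ⇒ OR 3`, `[0, 0.01) ⇒ OR 2`, or the three-class mixture with
low-frequency and common classes — so classes are hit in proportion to
their occupancy. Case-control samples use rejection sampling: haplotype
pairs drawn with replacement (random mating), affection drawn with
probability equal to the penetrance, until `R` cases and `S` controls
accumulate. Minor-allele coding is fixed from the population before
sampling so datasets from one population are comparable.

Missing genotypes follow a two-state Markov chain along the sequence, run
independently per individual from position 0 in the observed state:
observed stretches are `Exp(L(1 - lambda))` and missing stretches
`Exp(L * lambda)` on the unit-interval scale, so the expected observed
fraction is the call rate `lambda` and missingness is MCAR by
construction. At `lambda = 0.995` the chain's clustering interacts with
the CMC completeness rules severely: with hundreds of common variants per
sample, around 90% of individuals become unusable, and at
`lambda = 0.95` the CMC typically cannot be run at all — the robustness
contrast with the permutation tests is the point.

`run_study()` orchestrates replicated type I error and power estimates
over sample sizes, call rates and levels, excluding invalid analyses (CMC
with ddf ≤ 4) from rates and counting them separately;
`summarize_rejections()` supplies Clopper–Pearson exact binomial
intervals. All randomness descends from one master seed by drawing
per-replicate seeds from a single stream. We found empirically that
structured seed families (arithmetic progressions feeding different
pipeline stages in lockstep) can correlate Mersenne–Twister streams enough
to distort rejection-rate estimates by a couple of percentage points, so
derived-seed discipline is enforced throughout.

## Numerical choices and scale

* Ties in MAF at 0.5 declare the derived allele (1) minor; positions stay
  on the unit interval (the missingness process lives there), converted to
  base pairs only for display.
* Missing genotypes are stored as `NA`, never 0; the WSS missing-to-zero
  rule is applied inside its scoring only.
* G2SWEEP pivot tolerance `1e-8` relative to the largest original
  diagonal; the ddf > 4 validity rule is the guard near rank deficiency.
* Permutation defaults: `m` = 10,000, seeds mandatory; ties count toward
  the tail.
* The test suite validates the statistics against independent oracles:
  exhaustive enumeration of all 2×3 tables (trend = textbook
  Cochran–Armitage = `N rho^2`), exhaustive permutation distributions on
  6-individual datasets, textbook Hotelling with a standard inverse,
  closed-form coalescent expectations, and Monte-Carlo checks of the
  analytic power at five parameter points. Stochastic checks run at
  reduced scale — e.g. 500 null replicates on 10 kb loci with `m = 199`
  for calibration, and 30–50 full-scale populations for coalescent
  calibration — sizes chosen to keep Monte-Carlo error within the
  3-standard-error bands the tests assert.

## What the generator does and does not emulate

The synthetic data reproduce the MAF spectrum (most variants rare) and,
with the msprime backend, the negative-LD-dominated pairwise `r`
distribution characteristic of resequencing data, along with MCAR
missingness at realistic call rates. They do not include demographic
history (growth, structure), selection, genotyping error, missingness that
depends on genotype or phenotype, multi-allelic sites, or phasing
uncertainty. Passing tests therefore demonstrate correctness of the
statistics and calibration under the stated sampling model, not robustness
to confounding or to informative missingness — the permutation tests'
validity argument specifically assumes MCAR and no population
stratification.

## A worked example

```{r example, eval = FALSE}
pop <- simulate_population(n_hap = 2000, locus_length_bp = 100000, seed = 1)
classes <- rbind(risk_class(0, 0.01, 2))
model <- assign_disease_model(pop, classes, n_risk = 20, seed = 2)
gd <- sample_case_control(pop, model, R = 250, S = 250, seed = 3)
gd <- apply_missingness(gd, call_rate = 0.995, seed = 4)

bcca_test(gd)
ca_perm_test(gd, c("max", "sum"), m = 10000, seed = 5)
cmc_test(gd)
wss_test(gd, m = 10000, seed = 6)
```
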