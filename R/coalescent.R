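#' Simulate a haplotype population under the neutral coalescent
#'
#' Generates `n_hap` binary haplotypes at a locus of `locus_length_bp` base
#' pairs under a standard neutral coalescent with infinite-sites mutation at
#' per-nucleotide rate `mu` and effective diploid population size `Ne`, so
#' that the scaled mutation rate is `theta = 4 Ne mu L` and the expected
#' number of segregating sites is `theta * sum_{i=1}^{n_hap - 1} 1/i`.
#'
#' Two backends are available.  The `"internal"` backend is a self-contained
#' Hudson coalescent without recombination: exponential coalescence times,
#' Poisson mutations dropped on branches, mutant sites placed uniformly on
#' the unit interval.  Recombination does not change the expected number of
#' segregating sites, but it does reduce its replicate-to-replicate variance
#' and shapes LD, so studies of LD-sensitive behaviour should use the
#' `"msprime"` backend, a thin adapter that runs the msprime coalescent
#' simulator (with recombination at per-adjacent-nucleotide rate `rho`)
#' through the system `python` and parses its ms-format output.
#'
#' @param n_hap number of haplotypes (default 10,000).
#' @param locus_length_bp locus length in base pairs (default 100,000).
#' @param mu per-nucleotide mutation rate (default 2.5e-8).
#' @param rho per-adjacent-nucleotide recombination rate (default 1e-8;
#'   used by the `"msprime"` backend only).
#' @param Ne effective diploid population size (default 10,000).
#' @param backend `"internal"` or `"msprime"`.
#' @param seed RNG seed.
#' @return a [haplotype_population()].
#' @export
simulate_population <- function(n_hap = 10000L, locus_length_bp = 100000L,
                                mu = 2.5e-8, rho = 1e-8, Ne = 10000L,
                                backend = c("internal", "msprime"),
                                seed = NULL) {
  backend <- match.arg(backend)
  stopifnot(n_hap >= 2, mu > 0, Ne > 0, locus_length_bp >= 1)
  theta <- 4 * Ne * mu * locus_length_bp
  if (backend == "msprime")
    return(.simulate_msprime(n_hap, locus_length_bp, mu, rho, Ne, seed))
  if (!is.null(seed)) {
    restore <- .with_seed(seed)
    on.exit(restore())
  }
  n <- as.integer(n_hap)
  k <- n:2
  t_k <- stats::rexp(n - 1L, rate = k * (k - 1) / 2)  # coalescent units of 2Ne... (scaled out below)
  M_k <- stats::rpois(n - 1L, theta / 2 * k * t_k)    # mutations per interval
  lineages <- as.list(seq_len(n))
  total <- sum(M_k)
  carriers <- vector("list", total)
  nm <- 0L
  for (e in seq_len(n - 1L)) {
    kk <- n - e + 1L
    mcount <- M_k[e]
    if (mcount > 0L) {
      who <- sample.int(kk, mcount, replace = TRUE)
      for (w in who) {
        nm <- nm + 1L
        carriers[[nm]] <- lineages[[w]]
      }
    }
    pair <- sample.int(kk, 2L)
    i <- pair[1L]; j <- pair[2L]
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    lineages[[j]] <- lineages[[kk]]
    lineages[[kk]] <- NULL
  }
  if (nm == 0L) {
    pop <- haplotype_population(matrix(integer(0), n, 0), numeric(0),
                                locus_length_bp)
    return(pop)
  }
  positions <- sort(stats::runif(nm))
  H <- matrix(0L, nrow = n, ncol = nm)
  # sites sorted by position; mutations assigned to sites in random order so
  # allele frequency is independent of position
  shuffle <- sample.int(nm)
  for (s in seq_len(nm)) H[carriers[[shuffle[s]]], s] <- 1L
  haplotype_population(H, positions, locus_length_bp)
}

# msprime adapter: haploid samples from a population of 2*Ne haploids gives
# pairwise coalescence rate 1/(2 Ne) and theta = 4 Ne mu L, matching the
# diploid Wright-Fisher scaling of the internal backend.
.simulate_msprime <- function(n_hap, L, mu, rho, Ne, seed) {
  python <- Sys.which("python")
  if (python == "") stop("'python' not found on PATH; msprime backend unavailable")
  script <- system.file("python", "msprime_ms.py", package = "rvlocus")
  if (script == "") stop("bundled msprime adapter script not found")
  out <- tempfile(fileext = ".ms")
  args <- c(script, n_hap, L, mu, rho, Ne,
            if (is.null(seed)) sample.int(2^31 - 2L, 1L) else seed, out)
  status <- system2(python, shQuote(as.character(args)))
  if (status != 0) stop("msprime adapter failed with status ", status)
  pops <- read_ms(out, locus_length_bp = L)
  unlink(out)
  pops[[1L]]
}

#' Expected number of segregating sites
#'
#' Watterson's expectation `theta * sum_{i=1}^{n-1} 1/i` with
#' `theta = 4 Ne mu L`; unchanged by recombination.
#'
#' @param n_hap number of haplotypes.
#' @param locus_length_bp locus length (bp).
#' @param mu per-nucleotide mutation rate.
#' @param Ne effective diploid population size.
#' @return expected segregating-site count.
#' @export
expected_segsites <- function(n_hap, locus_length_bp = 100000L, mu = 2.5e-8,
                              Ne = 10000L) {
  theta <- 4 * Ne * mu * locus_length_bp
  theta * sum(1 / seq_len(n_hap - 1L))
}
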