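"""Run msprime and emit one replicate in Hudson ms text format.

Usage: msprime_ms.py n_hap L mu rho Ne seed out_file

Haploid samples are drawn from a population of 2*Ne haploid individuals, so
the pairwise coalescence rate is 1/(2 Ne) and theta = 4 Ne mu L, matching
the diploid Wright-Fisher scaling.  Mutations use the infinite-sites model
on a continuous genome; positions are emitted rescaled to [0, 1].
"""
import sys

import msprime


def main() -> None:
    n_hap, L = int(sys.argv[1]), float(sys.argv[2])
    mu, rho, ne = float(sys.argv[3]), float(sys.argv[4]), float(sys.argv[5])
    seed, out = int(sys.argv[6]), sys.argv[7]
    ts = msprime.sim_ancestry(
        samples=n_hap,
        ploidy=1,
        population_size=2 * ne,
        sequence_length=L,
        recombination_rate=rho,
        discrete_genome=False,
        random_seed=seed,
    )
    mts = msprime.sim_mutations(
        ts,
        rate=mu,
        model=msprime.BinaryMutationModel(),
        discrete_genome=False,
        random_seed=seed + 1,
    )
    positions = [site.position / L for site in mts.sites()]
    G = mts.genotype_matrix()  # sites x haplotypes
    with open(out, "w") as fh:
        fh.write("msprime ms-format output\n%d %d %d\n\n//\n" % (seed, 0, 0))
        fh.write("segsites: %d\n" % len(positions))
        if positions:
            fh.write("positions: " + " ".join("%.6f" % p for p in positions) + "\n")
            for h in range(G.shape[1]):
                fh.write("".join("1" if g else "0" for g in G[:, h]) + "\n")


if __name__ == "__main__":
    main()
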