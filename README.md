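# radsim — in-silico RAD-seq experiments for phylogenetic inference

RAD-seq (restriction-site associated DNA sequencing) reads fixed-length
fragments flanking the cut sites of a restriction enzyme, producing thousands
of loci scattered across a genome without prior marker development. Using it
*between* species raises a quantitative question: as divergence grows,
restriction sites disappear, homology between flanking tags becomes harder to
detect, and paralogous sites contaminate clusters — so at what divergence does
RAD-seq stop recovering the correct phylogeny?

`radsim` answers this by simulation with exact truth tracking. It simulates
genomes evolved along a known tree (Jukes–Cantor substitutions, no indels, so
every position keeps its ancestral coordinate), digests them in silico
(default enzyme Sbf1, motif `CCTGCAGG`), simulates reads (Poisson coverage,
uniform error), reassembles loci within specimens (stacks of identical reads,
single-linkage merging within a mismatch cap *M*, secondary-read attachment),
clusters consensus sequences across specimens (seeded local alignments gated
by a Karlin–Altschul E-value `E = K m n e^{-λS}`, union–find single linkage
with identity/overlap thresholds ≥ 0.35, plus a greedy-centroid baseline),
removes clusters where any specimen contributes two loci, concatenates the
surviving families (≥ 4 species) into a gap-filled supermatrix, and infers a
neighbor-joining tree with column-bootstrap supports. Because the truth of
every tag is known by construction, each stage reports exact error rates:
site conservation versus divergence, locus recovery/split/paralog-merge
rates, orthology-recovery efficiency (a family counts only if gathered
*complete and pure*), and the Robinson–Foulds distance to the true tree.

The package also includes the analytic design calculators used to plan real
experiments: mean coverage per locus per individual
`C = R / Σᵢ 2·Sᵢ` for a pool of N individuals with Sᵢ restriction sites each,
the Poisson sampling probability `P(X ≥ k)` that a locus is sequenced at
least k times, and the largest pool size achieving a target coverage.

## Worked example

A full experiment on the built-in balanced 12-taxon tree (tree height 0.15
substitutions/site per lineage, 8-Mb genomes, all defaults: 85-bp tags, 5%
heterozygosity, 10× coverage, 1% error):

```r
library(radsim)
cfg <- experiment_config(tree = balanced12_tree(), genome_length = 8e6,
                         bootstrap_reps = 100, seed = 42)
rep <- run_experiment(cfg)
print(rep)
#> <rad_experiment>
#>   taxa: 12 (0 dropped), reads: 29359, families: 464 (110 in supermatrix)
#>   mean stack recovery: 75.4%, RF distance to truth: 0, min support: 99
```

The inferred tree matches the true topology exactly (Robinson–Foulds distance
0) with bootstrap supports of 99–100 on every internal edge. The mean
within-specimen recovery (~75%) is lower than the headline per-locus rate
because a third of diploid loci are hemizygous (the motif was destroyed on
one haplotype by 5% heterozygosity) and receive half coverage.

The design calculators reproduce the standard coverage arithmetic:

```r
coverage_per_locus(1.5e8, 200, 2308)
#> <coverage_design> R=1.5e+08 reads, N=200 individuals, mean S=2308 sites -> C=162.48x per locus
p_locus_sequenced(1, 3)   # fraction of loci sequenced at least once at 3x
#> [1] 0.9502129
p_locus_sequenced(2, 10)  # ... at least twice at 10x
#> [1] 0.9995006
```

And the per-locus recovery of the stack assembler under the full noise model
(20,000 independent diploid loci, 85 bp, h = 0.05, 10×, 1% error, m=2, M=13):

```r
simulate_locus_recovery(20000, seed = 1)$recovery_rate
#> [1] 0.8619431
```

about 86% of loci retain at least one allele — the dominant loss mode is an
allele pair in which neither allele accumulates the two identical reads
needed to seed a stack.

See the vignette (`vignettes/radseq-in-silico.Rmd`) for the models, parameter
meanings, numerical choices, and the limits of what a neutral simulator can
emulate (notably: deep restriction-site conservation in real genomes is
inflated by selective constraint, which this simulator deliberately omits).

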