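---
title: "Simulating RAD-seq experiments for phylogenetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating RAD-seq experiments for phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsim)
```

## What the package simulates

Restriction-site associated DNA sequencing (RAD-seq) sequences fixed-length
fragments flanking the cut sites of a restriction enzyme, yielding thousands
of short loci scattered across a genome without prior marker development.
Whether those loci can support *interspecific* phylogenetics depends on three
quantities that all decay with divergence: the fraction of restriction sites
conserved between genomes, the detectability of homology between the flanking
tags, and the phylogenetic signal left in the resulting alignments.

`radsim` reconstructs this whole chain in silico, with exact positional truth
at every step:

1. **Genome simulation** (`generate_ancestor()`, `evolve_along_tree()`,
   `diploidize()`, `insert_duplications()`): an i.i.d. ancestor evolves along
   a known tree; each specimen receives a second haplotype; optional
   segmental duplications create genuine paralogs. Every position carries its
   ancestral coordinate and a duplication-lineage tag, so the orthology of
   every downstream tag is known by construction — the role whole-genome
   alignments play for real genomes.
2. **Digestion** (`find_sites()`, `extract_tags()`, `conservation_curve()`):
   exact motif matching (default Sbf1, `CCTGCAGG`), extraction of fixed-length
   tags on both sides of each site, and the conservation-versus-divergence
   relationship measured against the truth map.
3. **Read simulation** (`simulate_reads()`): Poisson coverage per locus,
   shared equally by the two alleles, with a uniform per-base error rate;
   plus the analytic design calculators `coverage_per_locus()`,
   `p_locus_sequenced()` and `max_pool_size()`.
4. **Within-specimen locus assembly** (`build_stacks()`, `merge_stacks()`,
   `attach_secondary()`, `call_consensus()`): stacks of strictly identical
   reads (minimum depth `m`), single-linkage merging of stacks within `M`
   mismatches into putative loci, attachment of leftover reads within `N_mm`
   mismatches of a frozen consensus, and truth-based recovery/split/
   paralog-merge metrics.
5. **Cross-specimen homology clustering** (`all_vs_all_hits()`,
   `single_linkage_cluster()`, `greedy_centroid_cluster()`,
   `filter_paralogous_clusters()`, `clustering_efficiency()`): seeded local
   alignments gated by a Karlin–Altschul E-value, union–find single linkage
   under identity and overlap thresholds, a greedy-centroid baseline, and
   removal of clusters in which any specimen contributes two loci.
6. **Phylogeny** (`align_family()`, `build_supermatrix()`,
   `distance_matrix()`, `nj_tree()`, `bootstrap_support()`,
   `rf_distance()`, `informative_loci_per_node()`): positional family
   alignments, a gap-filled concatenation restricted to families with at
   least `min_taxa` species, Jukes–Cantor distances with pairwise deletion,
   neighbor joining with a column bootstrap, and scoring against the true
   tree.

`run_experiment()` chains all stages from one `experiment_config()`;
`exec/radsim` exposes each stage as a shell subcommand.

## The mutation model

Evolution is substitution-only Jukes–Cantor, applied per branch as a single
Bernoulli pass: on a branch of length $d$ expected substitutions per site,
each site changes with probability $p = \tfrac{3}{4}(1 - e^{-4d/3})$,
uniformly to one of the three other bases. This reproduces the expected
p-distance of a continuous-time JC process without per-event bookkeeping.
There are **no indels** anywhere, which keeps positional truth exact and
makes family alignments positional (tags are anchored at the cut site).
Heterozygosity is applied the same way: haplotype b is haplotype a mutated
independently per site with probability `h`, so `h` is the realized average
allele distance — the generative rule behind a stated average divergence,
with uniform independent sites assumed.

Two consequences deserve emphasis:

* An 8-bp motif survives a pairwise path of $d$ substitutions/site in both
  leaves with probability $(1-p)^{16}$. At $d = 0.1$ per lineage that is
  roughly 45%; at $d = 0.65$ per lineage (1.3 pairwise) it is about
  $10^{-4}$. Real genomes retain far more sites at large divergences because
  restriction sites surviving tens of millions of years sit
  disproportionately in selectively constrained regions; a neutral,
  rate-homogeneous simulator (rate variation is an explicit non-goal) cannot
  reproduce that enrichment. Conservation results here are therefore
  validated against the $(1-p)^{16}$ oracle, not against any empirical
  conservation percentage.
* Because motif density is at equilibrium under the uniform model, sites
  present in any ancestor of a pair — including sites gained after the root —
  are genuine orthologs with valid coordinates, so conservation between two
  genomes depends only on their pairwise divergence.

## Key parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `motif` | `CCTGCAGG` | Sbf1 recognition site; 8 bp, GC-rich, palindromic, hence a rare cutter (one site per 65 kb of GC-balanced sequence) |
| `tag_len` | 85 bp | usable sequence of a 101-bp read after barcode and motif; 35 bp models 51-bp reads |
| `h` | 0.05 | per-site allele divergence, the upper bound of realistic polymorphism |
| `mean_coverage` | 10 | mean reads per locus; the two alleles share it equally (hemizygous loci get half) |
| `error_rate` | 0.01 | uniform per-base error, the upper bound of Illumina error estimates |
| `m`, `M`, `N_mm` | 2, 13, 9 | minimum stack depth; stack-merge mismatch cap; secondary-read cap. `M = 13` comfortably exceeds the ~4 mismatches between 5%-divergent alleles of an 85-bp tag, so heterozygosity does not split loci, while unrelated tags (~64 mismatches) never merge |
| `min_identity`, `min_overlap` | 0.35, 0.35 | permissive single-linkage thresholds; the E-value gate does the statistical filtering |
| `evalue_cut`, `word_size` | 1e-4, 11 | seeded-alignment significance cutoff and exact seed length |
| `min_taxa` | 4 | families below this species count carry no usable topological information |
| `bootstrap_reps` | 100 | column-bootstrap replicates |

## Coverage arithmetic

With `R` total reads shared by `N` pooled individuals carrying `S_i`
restriction sites each, the expected coverage per locus per individual is

$$C = \frac{R}{\sum_{i=1}^{N} 2 S_i},$$

counting two tags per site. Per-locus read counts are Poisson, so the
fraction of loci sequenced at least $k$ times is $P(\mathrm{Pois}(C) \ge k)$:
95.0% at least once at 3x, 99.3% at 5x, and 99.95% at least twice at 10x.
Because stacks require `m = 2` identical reads, recovery after assembly is
lower than these sampling bounds once heterozygosity and errors split reads
across distinct sequences: at 10x, 5% heterozygosity and 1% error, about
86–88% of loci retain at least one allele (the dominant failure mode is an
allele pair in which neither allele accumulates two error-free reads).
`max_pool_size()` inverts the formula; note it is the theoretical bound the
formula implies, with no safety margin for coverage variation between loci
or specimens.

## Numerical and algorithmic choices

* **Hit significance.** Local alignments (match +1, mismatch −2, gap open 5,
  gap extend 2) are scored and converted to $E = K m n e^{-\lambda S}$ with
  $\lambda$ solved from the ungapped score system at uniform composition
  (≈1.33) and $K = 0.621$, the standard ungapped value for these scores.
  Only accept/reject behaviour at `evalue_cut` matters; no attempt is made to
  match any particular BLAST build's scores. Seeds below 1.5 bits/base of
  entropy are masked, standing in for a low-complexity filter.
* **Overlap denominator.** The fraction of length covered by an alignment
  uses the longer of the two sequences — the conservative reading.
* **Ties.** Consensus ties break by the fixed base order A<C<G<T; secondary
  reads equidistant from two loci stay unattached; families are oriented from
  their lexicographically smallest member; supermatrix families concatenate
  in family-id order. These rules make every output deterministic given the
  seed.
* **Missing data.** A taxon absent from a family is gap-filled across that
  family's span; distances use pairwise deletion; a taxon pair sharing no
  ungapped column is an error rather than an imputed distance, because silent
  imputation distorts trees. Taxa appearing in no qualifying family are
  dropped from the supermatrix and reported.
* **Tree inference.** Neighbor joining on JC distances replaces
  likelihood-based inference to keep the package self-contained; the
  supermatrix can be exported in FASTA or relaxed PHYLIP for external ML
  tools. On additive matrices NJ is exact, and the column bootstrap
  (`bootstrap_support()`) measures signal the same way an alignment-level
  bootstrap does.
* **RNG.** One master seed; every stage derives a named substream
  (`substream_seed()`), so stages can be re-run in isolation and a full run
  is byte-reproducible.

## The built-in trees, and what deep divergence does

`ladder12_tree()` is an ultrametric 12-taxon caterpillar whose divergence
events are log-spaced from 0.05 to 0.65 substitutions/site per lineage —
pairwise divergences up to 1.3, emulating the depth range of a classic
multi-genome insect clade. Under the neutral model the deepest lineage
retains essentially no restriction site shared with any other taxon (the
$(1-p)^{16} \approx 10^{-4}$ arithmetic above), so a default-scale run
cannot place that taxon: the package reports it as dropped, or fails loudly
at the distance stage when a retained pair shares no columns. This is a
faithful property of neutral sequence at those depths, not an implementation
limit; the corresponding end-to-end expectation is exercised by the test
suite and documented as unattainable under the neutral model.

`balanced12_tree()` (two mirrored six-taxon clades, height 0.15) is the
strong-signal demonstration: every pairwise divergence stays within the range
where site conservation and homology detection both work at realistic genome
sizes. On 8-Mb genomes with all defaults, the full pipeline recovers the true
topology with Robinson–Foulds distance 0 and bootstrap supports of 95–100 on
every internal edge — the package's headline end-to-end property, asserted in
the test suite at a fixed seed.

Problem sizes used by the tests were chosen to make each property sharp at
its tolerance: 100-kb sequences for Jukes–Cantor and heterozygosity oracles
(4 standard errors), 20-Mb genomes for the conservation curve (~300 sites per
genome), 20,000 loci for recovery rates, 8-Mb genomes for the end-to-end run.

## Comparing the two clustering strategies

`compare_clusterers()` evaluates union–find single linkage (identity and
overlap thresholds on E-value-gated local hits) against greedy centroid
clustering (a single global-identity threshold, order-dependent) on synthetic
tag families with known truth (`simulate_tag_families()`, optionally with
paralogs and depth-dependent taxon dropout). The efficiency metric is strict:
a true family counts as recovered only when all its present members sit in
one cluster containing nothing else, so it combines sensitivity (gathering
orthologs) with specificity (excluding paralogs and chance matches). Two
regimes separate the methods:

* At permissive thresholds (0.35), greedy centroids absorb chance matches
  and moderately diverged paralogs — any sequence at ≥35% global identity to
  an earlier centroid joins it — while the E-value gate keeps such pairs out
  of the single-linkage graph. Single linkage also rides chains of closely
  related intermediates to gather members whose direct similarity is
  undetectable.
* At stringent thresholds (≥0.8), both methods fall apart on deep families,
  whose within-family identities sit far below the threshold.

## What passing tests do and do not show

The generator emulates: neutral substitution-only divergence, realistic
heterozygosity, Poisson coverage, uniform sequencing error, recent segmental
duplication. It does not emulate: indels, rate variation among sites or
lineages, selective constraint around restriction sites, GC heterogeneity,
PCR duplicates, coverage bias, incomplete lineage sorting or introgression.
Passing tests therefore validate the *pipeline machinery and its statistics*
— recovery arithmetic, clustering behaviour, supermatrix bookkeeping, tree
inference — under a clean model. They do not certify performance on real
data, where constraint inflates deep-site conservation (helping) and indels,
repeats and coverage structure violate the clean model (hurting).

## Known limitations

* Hemizygous loci receive half coverage by construction; there is no
  specimen-level coverage imbalance beyond a per-config mean.
* `find_sites()` handles non-palindromic motifs by scanning both strands but
  tag orientation assumes the palindromic default.
* The greedy-centroid baseline is deliberately minimal (input-order seeding,
  full-length identity) — it is a comparison foil, not a uclust
  re-implementation; likewise the stack assembler models only the
  depth/mismatch mechanics, not deleveraging heuristics.
* `rf_distance()` requires identical leaf sets; runs that drop taxa report
  `NA` rather than a pruned-tree distance.
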