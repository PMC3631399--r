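Package: radsim
Title: In Silico RAD-Seq Experiments for Phylogenetic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates restriction-site associated DNA (RAD-seq) experiments
    end to end: neutral genomes evolved along a known phylogeny with full
    positional truth tracking, in-silico restriction digestion and tag
    extraction, Poisson-coverage read simulation with uniform sequencing
    error, within-specimen locus assembly (stack formation, single-linkage
    merging under a mismatch cap, secondary-read attachment, consensus
    calling), cross-specimen homology clustering (seeded local-alignment
    hits gated by a Karlin-Altschul E-value, union-find single-linkage with
    identity and overlap thresholds, and a greedy-centroid baseline),
    paralog-cluster filtering, supermatrix concatenation, neighbor-joining
    with bootstrap support, and truth-based metrics (locus recovery, split
    and paralog-merge rates, orthology-recovery efficiency, Robinson-Foulds
    distance). Includes analytic coverage and pool-design calculators for
    planning multiplexed RAD-seq runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
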