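#' The built-in 12-taxon ladder tree
#'
#' An ultrametric caterpillar ("ladder") over 12 taxa whose divergence events
#' are log-spaced between `min_depth` and `max_depth` substitutions per site
#' per lineage (so the two lineages meeting at the root are `2 * max_depth`
#' apart, up to ~1.3 with the defaults). This emulates a clade whose node
#' depths span shallow to deep divergences without claiming any particular
#' real topology.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param min_depth,max_depth shallowest / deepest divergence (subst/site per
#'   lineage).
#' @param spacing `"log"` (default) or `"linear"` spacing of the divergence
#'   events between `min_depth` and `max_depth`.
#' @return a rooted `phylo` tree with taxa `sp01` ... `spNN`.
#' @export
ladder_tree <- function(n_taxa = 12, min_depth = 0.05, max_depth = 0.65,
                        spacing = c("log", "linear")) {
  stopifnot(n_taxa >= 3, min_depth > 0, max_depth >= min_depth)
  spacing <- match.arg(spacing)
  h <- if (spacing == "log")
    min_depth * (max_depth / min_depth)^(seq(0, n_taxa - 2) / (n_taxa - 2))
  else seq(min_depth, max_depth, length.out = n_taxa - 1)
  labs <- sprintf("sp%02d", seq_len(n_taxa))
  nwk <- sprintf("(%s:%g,%s:%g)", labs[1], h[1], labs[2], h[1])
  for (k in 3:n_taxa)
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, h[k - 1] - h[k - 2], labs[k], h[k - 1])
  ape::read.tree(text = paste0(nwk, ";"))
}

#' @rdname ladder_tree
#' @export
ladder12_tree <- function() ladder_tree(12, 0.05, 0.65)

#' A balanced 12-taxon demonstration tree
#'
#' Two mirrored 6-taxon clades, ultrametric, with every internal branch
#' substantial relative to the terminal branches (heights `scale * c(0.04,
#' 0.08, 0.11, 0.15)`). With the default scale, every pair of genomes is
#' close enough for restriction-site conservation and homology detection to
#' work at realistic genome sizes, which makes it the configuration of choice
#' for demonstrating full-pipeline topology recovery.
#'
#' @param scale multiplier on all branch lengths.
#' @return a rooted `phylo` tree over `sp01` ... `sp12`.
#' @export
balanced12_tree <- function(scale = 1) {
  half <- function(a, b, c, d, e, f) sprintf(
    "(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,(%s:%g,%s:%g):%g):%g",
    a, 0.04 * scale, b, 0.04 * scale, 0.04 * scale,
    c, 0.04 * scale, d, 0.04 * scale, 0.04 * scale, 0.03 * scale,
    e, 0.04 * scale, f, 0.04 * scale, 0.07 * scale, 0.04 * scale)
  ape::read.tree(text = sprintf("(%s,%s);",
    half("sp01", "sp02", "sp03", "sp04", "sp05", "sp06"),
    half("sp07", "sp08", "sp09", "sp10", "sp11", "sp12")))
}

#' Experiment configuration
#'
#' All parameters of the in-silico RAD-seq experiment with their defaults:
#' Sbf1 motif `CCTGCAGG`, 85-bp tags, 5\% heterozygosity, 10x mean coverage,
#' 1\% uniform error, stack parameters (m=2, M=13, N_mm=9), clustering
#' thresholds (identity 0.35, overlap 0.35, E-value 1e-4, word size 11),
#' supermatrix families of at least 4 species, and 100 bootstrap replicates.
#'
#' @param tree a `phylo`, a newick string, or the preset name `"ladder12"`.
#' @param genome_length ancestral genome length in bp.
#' @param gc ancestral GC content.
#' @param motif restriction enzyme recognition motif.
#' @param tag_len tag length in bp (85 for 101-bp reads, 35 for 51-bp reads).
#' @param h per-site heterozygosity.
#' @param mean_coverage mean reads per locus.
#' @param error_rate per-base sequencing error probability.
#' @param stacks a [stack_params()] list.
#' @param clustering a [cluster_params()] list.
#' @param min_taxa minimum species per family for the supermatrix.
#' @param bootstrap_reps bootstrap replicates.
#' @param n_dup,dup_len,dup_divergence optional segmental duplications
#'   inserted into the ancestor (defaults: none).
#' @param seed master seed; all stages derive named substreams from it.
#' @param out_dir optional output directory; when set, [run_experiment()]
#'   writes intermediate artifacts and the report there.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(tree = "ladder12", genome_length = 2e6, gc = 0.5,
                              motif = "CCTGCAGG", tag_len = 85, h = 0.05,
                              mean_coverage = 10, error_rate = 0.01,
                              stacks = stack_params(),
                              clustering = cluster_params(),
                              min_taxa = 4, bootstrap_reps = 100,
                              n_dup = 0, dup_len = 5000, dup_divergence = 0.05,
                              seed = 1, out_dir = NULL) {
  if (identical(tree, "ladder12")) tree <- ladder12_tree()
  tree <- as_species_tree(tree)
  if (length(tree$tip.label) < 3) stop("need at least 3 taxa")
  if (tag_len < 1) stop("tag_len must be positive")
  stopifnot(inherits(stacks, "stack_params"), inherits(clustering, "cluster_params"))
  structure(list(tree = tree, genome_length = as.integer(genome_length), gc = gc,
                 motif = motif, tag_len = as.integer(tag_len), h = h,
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 stacks = stacks, clustering = clustering,
                 min_taxa = as.integer(min_taxa),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 n_dup = as.integer(n_dup), dup_len = as.integer(dup_len),
                 dup_divergence = dup_divergence,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read a flat key=value configuration file
#'
#' INI-style `key = value` lines ('#' comments allowed); keys match the
#' arguments of [experiment_config()], with stack and clustering parameters
#' flattened as `m`, `M`, `N_mm`, `min_identity`, `min_overlap`,
#' `evalue_cut`, `word_size`, and `tree` given as a newick string, a file
#' path, or `"ladder12"`.
#'
#' @param path configuration file.
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  sp <- stack_params(m = num(vals[["m"]]) %||% 2, M = num(vals[["M"]]) %||% 13,
                     N_mm = num(vals[["N_mm"]]) %||% 9)
  cp <- cluster_params(min_identity = num(vals[["min_identity"]]) %||% 0.35,
                       min_overlap = num(vals[["min_overlap"]]) %||% 0.35,
                       evalue_cut = num(vals[["evalue_cut"]]) %||% 1e-4,
                       word_size = num(vals[["word_size"]]) %||% 11)
  tr <- vals[["tree"]] %||% "ladder12"
  if (!identical(tr, "ladder12") && file.exists(tr)) tr <- ape::read.tree(tr)
  experiment_config(
    tree = tr,
    genome_length = num(vals[["genome_length"]]) %||% 2e6,
    gc = num(vals[["gc"]]) %||% 0.5,
    motif = vals[["motif"]] %||% "CCTGCAGG",
    tag_len = num(vals[["tag_len"]]) %||% 85,
    h = num(vals[["h"]]) %||% 0.05,
    mean_coverage = num(vals[["mean_coverage"]]) %||% 10,
    error_rate = num(vals[["error_rate"]]) %||% 0.01,
    stacks = sp, clustering = cp,
    min_taxa = num(vals[["min_taxa"]]) %||% 4,
    bootstrap_reps = num(vals[["bootstrap_reps"]]) %||% 100,
    n_dup = num(vals[["n_dup"]]) %||% 0,
    dup_len = num(vals[["dup_len"]]) %||% 5000,
    dup_divergence = num(vals[["dup_divergence"]]) %||% 0.05,
    seed = num(vals[["seed"]]) %||% 1,
    out_dir = vals[["out_dir"]])
}

# consensus truth helpers -----------------------------------------------------

# For every putative locus of a specimen, the set of true locus ids among its
# stack reads, its majority id, and a purity flag.
locus_truth <- function(ls, truth) {
  lapply(ls$loci, function(l) {
    t <- truth[l$read_idx]
    tab <- sort(table(t), decreasing = TRUE)
    list(ids = names(tab), majority = names(tab)[1], pure = length(tab) == 1)
  })
}

#' Run the full in-silico RAD-seq experiment
#'
#' Executes genome simulation, digestion, read simulation, within-specimen
#' stack assembly, cross-specimen homology clustering, paralog filtering,
#' supermatrix construction and bootstrapped neighbor-joining, and scores the
#' result against the known species tree. All randomness derives from the
#' master seed through named substreams, so identical configurations give
#' byte-identical reports. Taxa whose loci enter no qualifying family are
#' dropped from the supermatrix (and listed in the report); the
#' Robinson-Foulds distance to the truth is reported only when every taxon
#' survived, as `NA` otherwise.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `rad_experiment`: a list of result tables (see
#'   the package vignette) including `conservation`, `stacks_metrics`,
#'   `pair_recovery`, `efficiency`, `gap_fraction`, `tree` (a
#'   `supported_tree`), `rf_distance`, `informative_loci` and `log`.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(config = config)

  # --- genomes ---------------------------------------------------------------
  say("simulating genomes (%d bp, %d taxa)", config$genome_length,
      length(config$tree$tip.label))
  anc <- generate_ancestor(config$genome_length, config$gc,
                           seed = substream_seed(seed, "ancestor"))
  if (config$n_dup > 0)
    anc <- insert_duplications(anc, config$n_dup, config$dup_len,
                               config$dup_divergence,
                               seed = substream_seed(seed, "dup"))
  leaves <- evolve_along_tree(anc, config$tree,
                              seed = substream_seed(seed, "evolve"))
  diploids <- lapply(leaves, function(g)
    diploidize(g, config$h, seed = substream_seed(seed, "diploid")))
  conservation <- conservation_curve(leaves, config$motif)

  # --- reads and stacks per specimen ----------------------------------------
  consensi <- character(0)
  cons_specimen <- character(0)
  cons_truth <- list()
  met_list <- list()
  n_reads_total <- 0
  for (sp in names(diploids)) {
    say("specimen %s: digest + reads + stacks", sp)
    tags <- digest_diploid(diploids[[sp]], config$motif, config$tag_len)
    reads <- simulate_reads(tags, config$mean_coverage, config$error_rate,
                            seed = substream_seed(seed, paste0("reads:", sp)))
    if (nrow(reads) == 0) stop(sprintf("stage stacks [%s]: no reads simulated (coverage %g)",
                                       sp, config$mean_coverage))
    n_reads_total <- n_reads_total + nrow(reads)
    ls <- assemble_loci(reads$seq, config$stacks)
    met_list[[sp]] <- stacks_metrics(ls, reads$locus)
    lt <- locus_truth(ls, reads$locus)
    ids <- sprintf("%s|L%04d", sp, seq_along(ls$loci))
    consensi <- c(consensi, stats::setNames(
      vapply(ls$loci, `[[`, character(1), "consensus"), ids))
    cons_specimen <- c(cons_specimen, stats::setNames(rep(sp, length(ids)), ids))
    cons_truth <- c(cons_truth, stats::setNames(lt, ids))
  }
  truth_majority <- stats::setNames(
    vapply(cons_truth, `[[`, character(1), "majority"), names(cons_truth))

  # --- homology clustering ---------------------------------------------------
  say("homology clustering (%d consensus sequences)", length(consensi))
  hits <- all_vs_all_hits(consensi, config$clustering)
  sl <- single_linkage_cluster(names(consensi), hits,
                               i = config$clustering$min_identity,
                               r = config$clustering$min_overlap)
  gc_clust <- greedy_centroid_cluster(consensi, config$clustering$min_identity)
  filt <- filter_paralogous_clusters(sl, cons_specimen)

  efficiency <- do.call(rbind, lapply(c(4, 6, 9), function(ms) data.frame(
    min_species = ms,
    single_linkage = clustering_efficiency(sl, truth_majority, cons_specimen, ms),
    greedy_centroid = clustering_efficiency(gc_clust, truth_majority,
                                            cons_specimen, ms))))

  pair_recovery <- pair_recovery_table(sl, truth_majority, cons_specimen, filt)

  # --- supermatrix and tree --------------------------------------------------
  say("supermatrix + neighbor joining + bootstrap")
  fams <- Filter(function(f) length(f) >= 2, filt$kept)
  fam_aln <- lapply(seq_along(fams), function(k) {
    f <- fams[[k]]
    seqs <- consensi[f]
    orient <- sl$orientation[f]
    seqs[orient == "-"] <- revcomp(seqs[orient == "-"])
    names(seqs) <- cons_specimen[f]
    align_family(seqs, id = sprintf("F%05d", k))
  })
  sm <- build_supermatrix(fam_aln, config$min_taxa)
  dropped <- setdiff(config$tree$tip.label, sm$taxa)
  tree <- bootstrap_support(sm, config$bootstrap_reps,
                            seed = substream_seed(seed, "bootstrap"))
  rf <- if (length(dropped) == 0)
    rf_distance(tree$tree, config$tree) else NA_integer_
  informative <- if (ape::is.rooted(config$tree))
    informative_loci_per_node(fam_aln, config$tree) else NULL

  report <- structure(list(
    config = config,
    conservation = conservation,
    stacks_metrics = data.frame(
      specimen = names(met_list),
      recovery_rate = vapply(met_list, `[[`, numeric(1), "recovery_rate"),
      split_rate = vapply(met_list, `[[`, numeric(1), "split_rate"),
      paralog_merge_rate = vapply(met_list, `[[`, numeric(1), "paralog_merge_rate"),
      n_true_loci = vapply(met_list, function(m) as.numeric(m$n_true_loci), numeric(1)),
      n_putative_loci = vapply(met_list, function(m) as.numeric(m$n_putative_loci), numeric(1)),
      row.names = NULL),
    n_reads = n_reads_total,
    n_families = length(fams),
    n_families_supermatrix = nrow(sm$spans),
    fraction_paralog_clusters_removed = filt$fraction_clusters_removed,
    fraction_tags_removed = filt$fraction_removed,
    efficiency = efficiency,
    pair_recovery = pair_recovery,
    supermatrix = sm,
    gap_fraction = sm$gap_fraction,
    tree = tree,
    dropped_taxa = dropped,
    rf_distance = rf,
    informative_loci = informative),
    class = "rad_experiment")
  if (!is.null(config$out_dir)) write_experiment(report, config$out_dir,
                                                 diploids = diploids)
  report
}

# Table-1-style per-pair accounting: for each taxon pair, how many ortholog
# tag pairs exist among the consensus sequences, which fraction was gathered
# in one cluster, and which fraction of those sit in paralog-flagged clusters.
pair_recovery_table <- function(clusters, truth, specimens, filt) {
  ids <- clusters$ids
  memb <- clusters$membership
  removed_members <- unlist(filt$removed, use.names = FALSE)
  taxa <- sort(unique(specimens))
  rows <- list()
  for (a_i in seq_along(taxa)[-length(taxa)]) {
    for (b_i in (a_i + 1):length(taxa)) {
      a <- taxa[a_i]; b <- taxa[b_i]
      ia <- ids[specimens[ids] == a]
      ib <- ids[specimens[ids] == b]
      common <- intersect(truth[ia], truth[ib])
      n <- length(common)
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_a = a, taxon_b = b, n_ortholog_pairs = 0L,
          retrieved = NA_real_, in_paralog_clusters = NA_real_)
        next
      }
      ma <- stats::setNames(memb[match(ia, ids)], truth[ia])
      mb <- stats::setNames(memb[match(ib, ids)], truth[ib])
      same <- vapply(common, function(tr) {
        ca <- unique(ma[names(ma) == tr]); cb <- unique(mb[names(mb) == tr])
        length(intersect(ca, cb)) > 0
      }, logical(1))
      par_a <- stats::setNames(ia %in% removed_members, truth[ia])
      with_par <- vapply(common[same], function(tr)
        any(par_a[names(par_a) == tr]), logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = a, taxon_b = b, n_ortholog_pairs = n,
        retrieved = mean(same),
        in_paralog_clusters = if (any(same)) mean(with_par) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.rad_experiment <- function(x, ...) {
  cat("<rad_experiment>\n")
  cat(sprintf("  taxa: %d (%d dropped), reads: %d, families: %d (%d in supermatrix)\n",
              length(x$config$tree$tip.label), length(x$dropped_taxa),
              x$n_reads, x$n_families, x$n_families_supermatrix))
  cat(sprintf("  mean stack recovery: %.1f%%, RF distance to truth: %s, min support: %s\n",
              100 * mean(x$stacks_metrics$recovery_rate),
              ifelse(is.na(x$rf_distance), "NA", x$rf_distance),
              if (length(x$tree$supports)) min(x$tree$supports) else "-"))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' JSON summary plus TSV tables, the supermatrix (FASTA and relaxed PHYLIP),
#' the inferred tree (newick with supports as node labels), and specimen
#' genomes as FASTA.
#'
#' @param report a `rad_experiment`.
#' @param dir output directory.
#' @param diploids optional list of diploid genomes to write.
#' @export
write_experiment <- function(report, dir, diploids = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$conservation, "conservation.tsv")
  tsv(report$stacks_metrics, "stacks_metrics.tsv")
  tsv(report$efficiency, "clustering_efficiency.tsv")
  tsv(report$pair_recovery, "pair_recovery.tsv")
  tsv(data.frame(taxon = names(report$gap_fraction),
                 gap_fraction = report$gap_fraction), "gap_fraction.tsv")
  tsv(report$informative_loci, "informative_loci.tsv")
  write_supermatrix_fasta(report$supermatrix, file.path(dir, "supermatrix.fasta"))
  write_supermatrix_phylip(report$supermatrix, file.path(dir, "supermatrix.phy"))
  ape::write.tree(report$tree$tree, file.path(dir, "tree.nwk"))
  ape::write.tree(report$config$tree, file.path(dir, "true_tree.nwk"))
  if (!is.null(diploids)) write_genomes_fasta(diploids, file.path(dir, "genomes"))
  summary <- list(
    n_reads = report$n_reads,
    n_families = report$n_families,
    n_families_supermatrix = report$n_families_supermatrix,
    fraction_paralog_clusters_removed = report$fraction_paralog_clusters_removed,
    fraction_tags_removed = report$fraction_tags_removed,
    mean_recovery_rate = mean(report$stacks_metrics$recovery_rate),
    dropped_taxa = report$dropped_taxa,
    rf_distance = report$rf_distance,
    min_support = if (length(report$tree$supports)) min(report$tree$supports) else NA,
    seed = report$config$seed)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the experiment in short-read mode
#'
#' Re-runs [run_experiment()] with 35-bp tags (the usable portion of 51-bp
#' reads) and the same seed, and reports the deep-node supports next to those
#' of the reference run for comparison: shorter tags carry less signal per
#' locus, which mostly affects the deepest bifurcations.
#'
#' @param config an [experiment_config()]; its `tag_len` is replaced by
#'   `tag_len_short`.
#' @param reference optional `rad_experiment` from the long-read run (computed
#'   if missing).
#' @param tag_len_short tag length of the short-read mode.
#' @return list with `short` and `long` (`rad_experiment`s) and
#'   `support_comparison` (data frame of minimum internal supports).
#' @export
short_read_mode <- function(config, reference = NULL, tag_len_short = 35) {
  if (tag_len_short < 1) stop("tag_len must be positive")
  cfg_short <- config
  cfg_short$tag_len <- as.integer(tag_len_short)
  cfg_short$out_dir <- NULL
  short <- run_experiment(cfg_short)
  long <- reference %||% run_experiment(config)
  cmp <- data.frame(
    mode = c(sprintf("%d bp", config$tag_len), sprintf("%d bp", tag_len_short)),
    min_support = c(min(long$tree$supports), min(short$tree$supports)),
    rf_distance = c(long$rf_distance, short$rf_distance))
  list(short = short, long = long, support_comparison = cmp)
}

#' Grid comparison of the two clustering algorithms
#'
#' Runs single-linkage (identity x overlap grid) and greedy-centroid
#' (identity grid) clustering on one set of sequences with known truth, and
#' reports the orthology-recovery efficiency per parameter combination and
#' per minimum-species stratum.
#'
#' @param seqs named character vector of sequences.
#' @param truth named character vector: true group per sequence id.
#' @param specimens named character vector: specimen per sequence id.
#' @param identities identity thresholds to test.
#' @param overlaps overlap thresholds for single-linkage.
#' @param min_species_list strata (minimum distinct species per true group).
#' @param params [cluster_params()] controlling hit generation (E-value,
#'   word size); thresholds come from the grids.
#' @return data frame with `method`, `identity`, `overlap`, `min_species`,
#'   `efficiency`.
#' @export
compare_clusterers <- function(seqs, truth, specimens,
                               identities = c(0.35, 0.9),
                               overlaps = 0.35,
                               min_species_list = c(4, 6, 9),
                               params = cluster_params()) {
  hits <- all_vs_all_hits(seqs, params)
  rows <- list()
  for (i in identities) {
    for (r in overlaps) {
      cs <- single_linkage_cluster(names(seqs), hits, i = i, r = r)
      for (ms in min_species_list)
        rows[[length(rows) + 1L]] <- data.frame(
          method = "single_linkage", identity = i, overlap = r,
          min_species = ms,
          efficiency = clustering_efficiency(cs, truth, specimens, ms))
    }
    gcs <- greedy_centroid_cluster(seqs, i)
    for (ms in min_species_list)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "greedy_centroid", identity = i, overlap = NA_real_,
        min_species = ms,
        efficiency = clustering_efficiency(gcs, truth, specimens, ms))
  }
  do.call(rbind, rows)
}

#' Simulate complete tag families along a tree
#'
#' Synthetic data for evaluating homology clustering in isolation: for each
#' family, a random ancestral tag is evolved along the tree (every taxon
#' keeps the locus, so family depth is controlled by the tree alone), and
#' optionally each family receives paralogous copies — the ancestral tag
#' mutated at per-site probability `paralog_divergence` and assigned to
#' random taxa with their own truth group.
#'
#' @param n_families number of families.
#' @param tree `phylo` or newick; branch lengths in substitutions/site.
#' @param tag_len tag length in bp.
#' @param n_paralogs paralogous copies per family.
#' @param paralog_divergence per-site divergence of each paralog from the
#'   family ancestor.
#' @param site_loss_motif_len when positive, each taxon is dropped from a
#'   family with the probability that a restriction motif of this length was
#'   destroyed on the taxon's root-to-tip path, so deeper taxa appear in
#'   fewer families (as they do after a real digestion); 0 keeps every taxon.
#' @param seed integer RNG seed.
#' @return list with `seqs`, `truth`, `specimens` (named vectors keyed by
#'   sequence id), ready for [compare_clusterers()].
#' @export
simulate_tag_families <- function(n_families, tree, tag_len = 85,
                                  n_paralogs = 0, paralog_divergence = 0.5,
                                  site_loss_motif_len = 0, seed = 1) {
  tree <- as_species_tree(tree)
  keep_prob <- rep(1, length(tree$tip.label))
  if (site_loss_motif_len > 0) {
    depths <- diag(ape::vcv(tree))[tree$tip.label]
    keep_prob <- (1 - jc_sub_prob(depths))^site_loss_motif_len
  }
  names(keep_prob) <- tree$tip.label
  seqs <- character(0); truth <- character(0); specimens <- character(0)
  for (f in seq_len(n_families)) {
    anc <- with_seed(substream_seed(seed, paste0("fam:", f)),
                     int_to_seq(sample.int(4L, tag_len, replace = TRUE)))
    leaves <- evolve_along_tree(haploid_genome("anc", anc), tree,
                                seed = substream_seed(seed, paste0("fam_evolve:", f)))
    if (site_loss_motif_len > 0) {
      keep <- with_seed(substream_seed(seed, paste0("fam_loss:", f)),
                        stats::runif(length(leaves)) < keep_prob[names(leaves)])
      if (sum(keep) < 2) next
      leaves <- leaves[keep]
    }
    ids <- sprintf("%s|fam%03d", names(leaves), f)
    seqs[ids] <- vapply(leaves, `[[`, character(1), "seq")
    truth[ids] <- sprintf("fam%03d", f)
    specimens[ids] <- names(leaves)
    if (n_paralogs > 0) {
      tx <- with_seed(substream_seed(seed, paste0("fam_par_tx:", f)),
                      sample(tree$tip.label, n_paralogs, replace = FALSE))
      for (k in seq_len(n_paralogs)) {
        pid <- sprintf("%s|fam%03d_par%d", tx[k], f, k)
        seqs[pid] <- with_seed(substream_seed(seed, paste0("fam_par:", f, ":", k)),
                               int_to_seq(mutate_sites(seq_to_int(anc),
                                                       paralog_divergence)))
        truth[pid] <- sprintf("fam%03d_par%d", f, k)
        specimens[pid] <- tx[k]
      }
    }
  }
  list(seqs = seqs, truth = truth, specimens = specimens)
}
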