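#' Stack-assembly parameters
#'
#' `m` is the minimum number of strictly identical reads needed to form a
#' stack; `M` the maximum Hamming distance between stacks merged into one
#' putative locus (single linkage); `N_mm` the maximum Hamming distance for
#' attaching a leftover (secondary) read to a locus consensus. The defaults
#' (m=2, M=13, N_mm=9) are chosen so that, on 85-bp tags, the two alleles of
#' a 5%-heterozygous locus (about 4 mismatches apart) merge into one locus
#' while unrelated loci (about 64 mismatches apart) never do.
#'
#' @param m minimum stack depth (>= 1).
#' @param M maximum mismatches between stacks within a locus (>= 0).
#' @param N_mm maximum mismatches to attach a secondary read (>= 0).
#' @return a validated list of class `stack_params`.
#' @export
stack_params <- function(m = 2, M = 13, N_mm = 9) {
  if (m < 1 || M < 0 || N_mm < 0) stop("require m >= 1, M >= 0, N_mm >= 0")
  structure(list(m = as.integer(m), M = as.integer(M), N_mm = as.integer(N_mm)),
            class = "stack_params")
}

#' Form stacks of strictly identical reads
#'
#' Groups one specimen's reads by exact sequence equality; groups of size >=
#' `m` become stacks, all remaining reads are returned as secondary reads.
#' Stacks are ordered by decreasing depth, ties broken by sequence, so the
#' result is independent of read order.
#'
#' @param reads character vector of read sequences (equal length).
#' @param m minimum stack depth.
#' @return an object of class `stack_set`: list with `reads` (the input),
#'   `stacks` (data frame `seq`, `depth`), `stack_reads` (list of read index
#'   vectors per stack) and `secondary` (read indices).
#' @export
build_stacks <- function(reads, m = 2) {
  if (length(reads) && length(unique(nchar(reads))) != 1)
    stop("mixed read lengths")
  groups <- split(seq_along(reads), reads)
  depth <- lengths(groups)
  is_stack <- depth >= m
  o <- order(-depth[is_stack], names(groups)[is_stack])
  stacks <- data.frame(seq = names(groups)[is_stack][o],
                       depth = unname(depth[is_stack][o]),
                       stringsAsFactors = FALSE)
  structure(list(reads = reads,
                 m = as.integer(m),
                 stacks = stacks,
                 stack_reads = unname(groups[is_stack][o]),
                 secondary = sort(unlist(groups[!is_stack], use.names = FALSE))),
            class = "stack_set")
}

#' @export
print.stack_set <- function(x, ...) {
  cat(sprintf("<stack_set> %d reads -> %d stacks (m=%d), %d secondary\n",
              length(x$reads), nrow(x$stacks), x$m, length(x$secondary)))
  invisible(x)
}

#' Merge stacks into putative loci
#'
#' Single-linkage clustering of stacks: two stacks are linked when their
#' Hamming distance is at most `M`, and putative loci are the connected
#' components of that relation (so a chain A-B, B-C joins A and C even when
#' they differ by more than `M`). Each locus gets a consensus by
#' depth-weighted majority ([call_consensus()]), computed before any
#' secondary-read attachment and then frozen.
#'
#' @param x a `stack_set` from [build_stacks()].
#' @param M maximum mismatches between linked stacks.
#' @return an object of class `locus_set`: list with `reads`, `secondary`,
#'   `M`, and `loci`, a list where each locus has `stacks` (row indices into
#'   `x$stacks`), `seqs`, `depths`, `read_idx`, `consensus`, `depth`
#'   (summed stack depths).
#' @export
merge_stacks <- function(x, M = 13) {
  stopifnot(inherits(x, "stack_set"))
  n <- nrow(x$stacks)
  loci <- list()
  if (n > 0) {
    comp <- if (n == 1) 1L else {
      d <- hamming_matrix_cpp(x$stacks$seq)
      pairs <- which(d <= M & upper.tri(d), arr.ind = TRUE)
      uf_components(n, pairs[, 1], pairs[, 2])
    }
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k)
      loci[[k]] <- list(
        stacks = idx,
        seqs = x$stacks$seq[idx],
        depths = x$stacks$depth[idx],
        read_idx = sort(unlist(x$stack_reads[idx], use.names = FALSE)),
        consensus = call_consensus(x$stacks$seq[idx], x$stacks$depth[idx]),
        depth = sum(x$stacks$depth[idx]),
        attached = integer(0))
    }
  }
  structure(list(reads = x$reads, loci = loci, secondary = x$secondary,
                 M = as.integer(M)),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d putative loci from %d reads (M=%d), %d secondary\n",
              length(x$loci), length(x$reads), x$M, length(x$secondary)))
  invisible(x)
}

#' Depth-weighted consensus of a locus
#'
#' Per column, the base with the largest summed stack depth; ties are broken
#' by the fixed base order A < C < G < T.
#'
#' @param seqs stack sequences (equal length).
#' @param depths stack depths (defaults to 1 each).
#' @return the consensus DNA string.
#' @export
call_consensus <- function(seqs, depths = rep(1, length(seqs))) {
  if (!length(seqs)) stop("need at least one sequence")
  if (length(seqs) == 1) return(seqs)
  L <- nchar(seqs[1])
  m <- vapply(seqs, seq_to_int, integer(L))           # L x n
  counts <- matrix(0, nrow = 4, ncol = L)
  for (j in seq_along(seqs))
    counts[cbind(m[, j], seq_len(L))] <- counts[cbind(m[, j], seq_len(L))] + depths[j]
  # max.col with ties.method "first" on the transpose picks A<C<G<T on ties
  int_to_seq(max.col(t(counts), ties.method = "first"))
}

#' Attach secondary reads to putative loci
#'
#' Each secondary read is compared with every locus consensus; it attaches to
#' the unique nearest locus if that Hamming distance is at most `N_mm`. Ties
#' between loci, and distances above `N_mm`, leave the read unattached.
#' Attachment only increases locus depth (to better estimate coverage); it
#' never changes the frozen consensus and never founds a new locus.
#'
#' @param ls a `locus_set` from [merge_stacks()].
#' @param N_mm maximum mismatches to the consensus (boundary inclusive).
#' @return the `locus_set` with per-locus `attached` read indices, updated
#'   `depth`, and an `unattached` element.
#' @export
attach_secondary <- function(ls, N_mm = 9) {
  stopifnot(inherits(ls, "locus_set"))
  sec <- ls$secondary
  ls$unattached <- sec
  if (!length(sec) || !length(ls$loci)) return(ls)
  cons <- vapply(ls$loci, `[[`, character(1), "consensus")
  d <- hamming_cross_cpp(ls$reads[sec], cons)
  best <- apply(d, 1, min)
  n_best <- rowSums(d == best)
  target <- max.col(-d, ties.method = "first")
  ok <- best <= N_mm & n_best == 1
  for (k in unique(target[ok])) {
    got <- sec[ok & target == k]
    ls$loci[[k]]$attached <- got
    ls$loci[[k]]$depth <- ls$loci[[k]]$depth + length(got)
  }
  ls$unattached <- sec[!ok]
  ls
}

#' Assemble putative loci from reads
#'
#' Convenience wrapper running [build_stacks()], [merge_stacks()] and
#' [attach_secondary()] with one parameter set.
#'
#' @param reads character vector of read sequences.
#' @param params a [stack_params()] list.
#' @return a `locus_set`.
#' @export
assemble_loci <- function(reads, params = stack_params()) {
  stopifnot(inherits(params, "stack_params"))
  attach_secondary(merge_stacks(build_stacks(reads, params$m), params$M),
                   params$N_mm)
}

#' Truth-based metrics for within-specimen locus assembly
#'
#' A true locus counts as recovered when at least one putative locus contains
#' reads from it among its member stacks (secondary attachments estimate
#' coverage only and do not count as recovery). The split rate is the
#' fraction of recovered true loci whose stack reads are spread over more
#' than one putative locus; the paralog-merge rate is the fraction of
#' putative loci whose stacks contain reads from more than one true locus.
#' Denominators: true loci with at least one read in the input (recovery,
#' split) and putative loci (paralog merge).
#'
#' @param ls a `locus_set`.
#' @param truth character vector: the true locus id of each read (parallel to
#'   the reads passed to [build_stacks()]).
#' @return list with `recovery_rate`, `split_rate`, `paralog_merge_rate`,
#'   `n_true_loci`, `n_putative_loci`.
#' @export
stacks_metrics <- function(ls, truth) {
  stopifnot(inherits(ls, "locus_set"), length(truth) == length(ls$reads))
  true_present <- unique(truth)
  per_locus_truth <- lapply(ls$loci, function(l) unique(truth[l$read_idx]))
  covered <- unique(unlist(per_locus_truth))
  recovery <- length(intersect(true_present, covered)) / length(true_present)
  hits <- table(unlist(per_locus_truth)) # putative loci containing each true locus
  split_rate <- if (length(covered)) sum(hits > 1) / length(covered) else 0
  paralog <- if (length(ls$loci))
    mean(vapply(per_locus_truth, length, integer(1)) > 1) else 0
  list(recovery_rate = recovery, split_rate = split_rate,
       paralog_merge_rate = paralog,
       n_true_loci = length(true_present), n_recovered = length(covered),
       n_putative_loci = length(ls$loci))
}

#' Simulate many independent diploid loci and measure recovery
#'
#' Monte-Carlo estimate of the within-specimen recovery rate under the full
#' noise model: for each locus an allele pair is drawn (a random tag and a
#' copy mutated per site with probability `h`), read counts are Poisson with
#' mean `mean_coverage` per locus shared between alleles, reads receive
#' uniform per-base errors, and loci are assembled with [assemble_loci()].
#' Loci are simulated in chunks processed as one specimen batch each;
#' chunking does not affect per-locus recovery because unrelated random tags
#' are never within the merge threshold of each other.
#'
#' @param n_loci number of independent loci.
#' @param tag_len tag length in bp.
#' @param h per-site allele divergence (heterozygosity).
#' @param mean_coverage mean reads per locus.
#' @param error_rate per-base sequencing error probability.
#' @param params a [stack_params()] list.
#' @param seed integer RNG seed.
#' @param chunk loci per batch.
#' @return list with `recovery_rate`, `split_rate`, `paralog_merge_rate`,
#'   `n_loci` (loci with at least one read, the recovery denominator).
#' @export
simulate_locus_recovery <- function(n_loci = 20000, tag_len = 85, h = 0.05,
                                    mean_coverage = 10, error_rate = 0.01,
                                    params = stack_params(), seed, chunk = 250) {
  n_done <- 0
  recovered <- 0
  split <- 0
  covered_total <- 0
  paralog <- 0
  n_putative <- 0
  batch_i <- 0
  while (n_done < n_loci) {
    batch_i <- batch_i + 1
    nb <- min(chunk, n_loci - n_done)
    sseed <- substream_seed(seed, paste0("locus_recovery:", batch_i))
    tags <- with_seed(sseed, {
      a <- replicate(nb, sample.int(4L, tag_len, replace = TRUE), simplify = FALSE)
      b <- lapply(a, mutate_sites, p = h)
      data.frame(specimen = "sim",
                 locus = rep(sprintf("L%d_%d", batch_i, seq_len(nb)), 2),
                 allele = rep(c("a", "b"), each = nb),
                 seq = vapply(c(a, b), int_to_seq, character(1)),
                 stringsAsFactors = FALSE)
    })
    reads <- simulate_reads(tags, mean_coverage, error_rate,
                            seed = substream_seed(seed, paste0("reads:", batch_i)))
    if (nrow(reads) == 0) { n_done <- n_done + nb; next }
    ls <- assemble_loci(reads$seq, params)
    met <- stacks_metrics(ls, reads$locus)
    recovered <- recovered + met$n_recovered
    covered_total <- covered_total + met$n_true_loci
    split <- split + met$split_rate * met$n_recovered
    paralog <- paralog + met$paralog_merge_rate * met$n_putative_loci
    n_putative <- n_putative + met$n_putative_loci
    n_done <- n_done + nb
  }
  list(recovery_rate = recovered / covered_total,
       split_rate = if (recovered) split / recovered else 0,
       paralog_merge_rate = if (n_putative) paralog / n_putative else 0,
       n_loci = covered_total)
}

#' Write putative loci to TSV
#'
#' @param ls a `locus_set`.
#' @param specimen specimen label for the output.
#' @param path output file.
#' @export
write_loci_tsv <- function(ls, specimen, path) {
  df <- data.frame(
    specimen = specimen,
    locus_id = seq_along(ls$loci),
    consensus = vapply(ls$loci, `[[`, character(1), "consensus"),
    depth = vapply(ls$loci, function(l) as.numeric(l$depth), numeric(1)),
    n_stacks = vapply(ls$loci, function(l) length(l$stacks), integer(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
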