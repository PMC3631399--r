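#' Simulate RAD-seq reads from a diploid tag set
#'
#' Coverage is Poisson at the locus level: each locus (site x side) receives
#' on average `mean_coverage` reads, shared equally by its alleles. This is
#' realized by thinning: every allele tag draws an independent
#' `Poisson(mean_coverage * allele_share)` read count, which for a diploid
#' locus with both alleles present is exactly "total ~ Poisson(lambda), each
#' read a fair coin between alleles", and gives hemizygous loci the halved
#' coverage their single allele would receive on a real machine. Each read
#' base is substituted independently with probability `error_rate`, uniformly
#' to one of the three other bases. Reads carry hidden truth labels (locus,
#' side, allele) consumed only by evaluation functions, never by clustering.
#'
#' @param tags a tag table from [digest_diploid()] (all tags equal length).
#' @param mean_coverage mean reads per locus (lambda >= 0).
#' @param error_rate per-base error probability, in `[0, 0.5)`.
#' @param seed integer RNG seed.
#' @param allele_share fraction of locus coverage per allele tag (0.5 for
#'   diploid tag sets; set to 1 for haploid tag sets).
#' @return data frame with columns `read_id`, `specimen`, `locus`, `allele`,
#'   `seq`.
#' @export
simulate_reads <- function(tags, mean_coverage, error_rate = 0, seed,
                           allele_share = 0.5) {
  if (mean_coverage < 0) stop("mean_coverage must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  empty <- data.frame(read_id = character(0), specimen = character(0),
                      locus = character(0), allele = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0) {
    if (mean_coverage > 0) warning("empty tag set: no reads simulated")
    return(empty)
  }
  lens <- nchar(tags$seq)
  if (length(unique(lens)) != 1) stop("tags must all have the same length")
  L <- lens[1]
  with_seed(seed, {
    n <- stats::rpois(nrow(tags), mean_coverage * allele_share)
    idx <- rep(seq_len(nrow(tags)), n)
    if (length(idx) == 0) empty else {
    codes <- matrix(0L, nrow = nrow(tags), ncol = L)
    for (i in seq_len(nrow(tags))) codes[i, ] <- seq_to_int(tags$seq[i])
    reads <- codes[idx, , drop = FALSE]
    if (error_rate > 0) {
      err <- which(stats::runif(length(reads)) < error_rate)
      if (length(err))
        reads[err] <- ((reads[err] - 1L + sample(3L, length(err), replace = TRUE)) %% 4L) + 1L
    }
    data.frame(read_id = sprintf("%s_r%06d", tags$specimen[idx], seq_along(idx)),
               specimen = tags$specimen[idx],
               locus = tags$locus[idx],
               allele = tags$allele[idx],
               seq = apply(reads, 1, int_to_seq),
               stringsAsFactors = FALSE)
    }
  })
}

#' Mean sequencing coverage per locus per individual
#'
#' For a multiplexed run, `C = R / sum_i(2 * S_i)`: the total read number
#' divided by the total number of RAD tags in the pool, counting two tags
#' (one per side) for every restriction site of every individual.
#'
#' @param R total reads in the run.
#' @param N number of pooled individuals.
#' @param S restriction-site counts per individual (recycled to length `N`).
#' @return an object of class `coverage_design` with elements `R`, `N`, `S`
#'   and the resulting coverage `C`.
#' @examples
#' coverage_per_locus(1.5e8, 200, 2308)$C
#' @export
coverage_per_locus <- function(R, N, S) {
  if (R <= 0 || N <= 0) stop("R and N must be positive")
  S <- rep_len(S, N)
  if (any(S <= 0)) stop("site counts must be positive")
  structure(list(R = R, N = N, S = S, C = R / sum(2 * S)),
            class = "coverage_design")
}

#' @export
print.coverage_design <- function(x, ...) {
  cat(sprintf("<coverage_design> R=%g reads, N=%d individuals, mean S=%.0f sites -> C=%.2fx per locus\n",
              x$R, x$N, mean(x$S), x$C))
  invisible(x)
}

#' Probability that a locus is sequenced at least k times
#'
#' Read counts per locus are Poisson, so the proportion of loci sequenced at
#' least `k` times at mean coverage `lambda` is `P(X >= k)` for
#' `X ~ Poisson(lambda)`, computed in closed form.
#'
#' @param k minimum read count (>= 0).
#' @param lambda mean coverage per locus (>= 0).
#' @return the probability, vectorized over `k` and `lambda`.
#' @examples
#' p_locus_sequenced(1, 3)  # 1 - exp(-3), about 0.95
#' p_locus_sequenced(2, 10) # 1 - 11 exp(-10), about 0.9995
#' @export
p_locus_sequenced <- function(k, lambda) {
  if (any(k < 0) || any(lambda < 0)) stop("k and lambda must be >= 0")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Largest pool size meeting a target coverage
#'
#' Largest number of individuals `N` such that
#' `coverage_per_locus(R, N, mean_S)$C >= target_C`.
#'
#' @param R total reads in the run.
#' @param target_C required mean coverage per locus per individual.
#' @param mean_S mean restriction-site count per genome.
#' @return integer pool size.
#' @examples
#' max_pool_size(1.5e8, 10, 2308) # pooling capacity of one flow-cell lane
#' @export
max_pool_size <- function(R, target_C, mean_S) {
  if (R <= 0 || target_C <= 0 || mean_S <= 0) stop("all inputs must be positive")
  N <- floor(R / (2 * mean_S * target_C))
  if (N < 1) stop("target coverage unreachable even with a single individual")
  as.integer(N)
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output uses a constant quality symbol ("I"): the simulator models
#' errors directly, not quality-dependent error profiles. Truth labels go to
#' a sidecar TSV keyed by read id.
#'
#' @param reads a read table from [simulate_reads()].
#' @param path output file; format chosen by extension (`.fastq`/`.fq` for
#'   FASTQ, FASTA otherwise).
#' @param truth_path optional path for the sidecar truth TSV.
#' @export
write_reads <- function(reads, path, truth_path = NULL) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  if (grepl("\\.(fastq|fq)$", path)) {
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  strrep("I", nchar(reads$seq))))
  } else {
    Biostrings::writeXStringSet(ss, path)
  }
  if (!is.null(truth_path))
    utils::write.table(reads[, c("read_id", "specimen", "locus", "allele")],
                       truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
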