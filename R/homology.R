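#' Homology-clustering parameters
#'
#' Defaults follow common practice for clustering RAD consensus sequences
#' across divergent taxa: permissive identity and overlap thresholds (0.35),
#' an E-value cutoff of 1e-4 stringent enough to exclude chance similarities
#' between unrelated tags, and 11-bp exact seeds.
#'
#' @param min_identity minimum identity fraction in the aligned region.
#' @param min_overlap minimum fraction of the longer sequence covered by the
#'   alignment.
#' @param evalue_cut E-value threshold for accepting a pair hit.
#' @param word_size exact seed length (>= 4).
#' @return a validated list of class `cluster_params`.
#' @export
cluster_params <- function(min_identity = 0.35, min_overlap = 0.35,
                           evalue_cut = 1e-4, word_size = 11) {
  if (min_identity < 0 || min_identity > 1 || min_overlap < 0 || min_overlap > 1)
    stop("identity and overlap thresholds must be in [0,1]")
  if (evalue_cut <= 0) stop("evalue_cut must be positive")
  if (word_size < 4) stop("word_size must be >= 4")
  structure(list(min_identity = min_identity, min_overlap = min_overlap,
                 evalue_cut = evalue_cut, word_size = as.integer(word_size)),
            class = "cluster_params")
}

# Karlin-Altschul lambda for the +1/-2 score system at uniform base
# composition: the positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- local({
  cache <- new.env(parent = emptyenv())
  function(match = 1, mismatch = -2) {
    key <- paste(match, mismatch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    l <- stats::uniroot(f, c(1e-6, 10))$root
    cache[[key]] <- l
    l
  }
})

# Standard ungapped K for the +1/-2 nucleotide score system. Only the
# accept/reject behaviour at the E-value cutoff matters, not score parity
# with any particular BLAST build.
KA_K <- 0.621

# Seed words passing the low-complexity filter (>= min_bits bits/base).
seed_words <- function(seq, w, min_bits = 1.5) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1)
  words <- substring(seq, starts, starts + w - 1)
  keep <- vapply(unique(words), word_entropy, numeric(1)) >= min_bits
  unique(words)[keep]
}

#' All-against-all local-alignment hits
#'
#' For every ordered pair of sequences sharing at least one exact,
#' non-low-complexity word of `word_size` bases on either strand, a gapped
#' local alignment (match +1, mismatch -2, gap open 5, gap extend 2) is
#' computed and its significance assessed with the Karlin-Altschul formula
#' `E = K m n exp(-lambda S)` for the ungapped score system. Hits with
#' `E <= evalue_cut` are reported with identity (matches / aligned columns),
#' overlap (aligned columns / length of the longer sequence) and strand; when
#' both strands yield a hit for a pair the better E-value wins.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @param params a [cluster_params()] list.
#' @return data frame of class `pair_hits`: `query`, `subject`, `identity`,
#'   `overlap`, `evalue`, `strand`, `score`, `aln_len`.
#' @export
all_vs_all_hits <- function(seqs, params = cluster_params()) {
  if (length(seqs) < 2) stop("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  w <- params$word_size
  ids <- names(seqs)
  n <- length(seqs)
  rcs <- revcomp(seqs)
  fw <- lapply(seqs, seed_words, w = w)
  rw <- lapply(rcs, seed_words, w = w)
  # word -> sequence index, forward strand
  fw_idx <- data.frame(word = unlist(fw, use.names = FALSE),
                       i = rep(seq_len(n), lengths(fw)))
  rw_idx <- data.frame(word = unlist(rw, use.names = FALSE),
                       i = rep(seq_len(n), lengths(rw)))
  pair_key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  cand <- list(`+` = integer(0), `-` = integer(0))
  # forward/forward sharing -> + strand candidates
  for (grp in split(fw_idx$i, fw_idx$word)) {
    u <- unique(grp)
    if (length(u) > 1) {
      cp <- utils::combn(u, 2)
      cand$`+` <- c(cand$`+`, pair_key(cp[1, ], cp[2, ]))
    }
  }
  # forward word of i found among reverse-complement words of j -> - strand
  shared <- merge(fw_idx, rw_idx, by = "word")
  keep <- shared$i.x != shared$i.y
  cand$`-` <- unique(pair_key(shared$i.x[keep], shared$i.y[keep]))
  cand$`+` <- unique(cand$`+`)
  lambda <- ka_lambda()
  rows <- list()
  for (strand in c("+", "-")) {
    keys <- cand[[strand]]
    if (!length(keys)) next
    i <- ((keys - 1) %/% n) + 1
    j <- ((keys - 1) %% n) + 1
    subj <- if (strand == "+") seqs[j] else rcs[j]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(unname(seqs[i])),
      Biostrings::DNAStringSet(unname(subj)),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    S <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    ev <- KA_K * nchar(seqs[i]) * nchar(seqs[j]) * exp(-lambda * S)
    ok <- ev <= params$evalue_cut & alen > 0
    if (any(ok))
      rows[[strand]] <- data.frame(
        query = ids[i][ok], subject = ids[j][ok],
        identity = (Biostrings::nmatch(aln) / alen)[ok],
        overlap = (alen / pmax(nchar(seqs[i]), nchar(seqs[j])))[ok],
        evalue = ev[ok], strand = strand,
        score = S[ok], aln_len = alen[ok],
        stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), subject = character(0),
               identity = numeric(0), overlap = numeric(0),
               evalue = numeric(0), strand = character(0),
               score = numeric(0), aln_len = numeric(0))
  # best E-value per unordered pair supplies identity/overlap
  if (nrow(hits) > 1) {
    key <- paste(pmin(hits$query, hits$subject), pmax(hits$query, hits$subject))
    hits <- hits[order(key, hits$evalue), ]
    hits <- hits[!duplicated(paste(pmin(hits$query, hits$subject),
                                   pmax(hits$query, hits$subject))), ]
  }
  rownames(hits) <- NULL
  class(hits) <- c("pair_hits", "data.frame")
  hits
}

#' Write hits in 12-column tabular format
#'
#' Columns follow the classic tabular convention: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score. Coordinates and gap counts are not
#' tracked by the hit table and are written as the full-tag span and zero;
#' the bit score is `(lambda S - ln K) / ln 2`.
#'
#' @param hits a `pair_hits` table.
#' @param seqs the sequences the hits were computed on.
#' @param path output file.
#' @export
write_hits_tabular <- function(hits, seqs, path) {
  lambda <- ka_lambda()
  df <- data.frame(
    query = hits$query, subject = hits$subject,
    pident = round(100 * hits$identity, 2),
    length = hits$aln_len,
    mismatch = round(hits$aln_len * (1 - hits$identity)),
    gapopen = 0L,
    qstart = 1L, qend = nchar(seqs[hits$query]),
    sstart = 1L, send = nchar(seqs[hits$subject]),
    evalue = signif(hits$evalue, 3),
    bitscore = round((lambda * hits$score - log(KA_K)) / log(2), 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Build a cluster_set object from membership labels.
new_cluster_set <- function(ids, membership, method, orientation = NULL) {
  names(membership) <- ids
  structure(list(ids = ids, membership = membership, method = method,
                 orientation = orientation),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d sequences in %d families (%s)\n",
              length(x$ids), length(unique(x$membership)), x$method))
  invisible(x)
}

#' Families of a cluster set
#'
#' @param x a `cluster_set`.
#' @return list of character vectors of member ids.
#' @export
cluster_families <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  unname(split(x$ids, x$membership))
}

#' Single-linkage clustering of pair hits (union-find)
#'
#' Joins two sequences whenever a hit between them has identity `>= i` and
#' overlap `>= r`; families are the connected components of the resulting
#' graph (computed with a union-find structure), and sequences with no
#' qualifying edge are singletons. Member orientations are propagated from
#' the lexicographically smallest member of each family along qualifying
#' edges, so families joined through minus-strand hits can be oriented
#' consistently downstream.
#'
#' @param ids character vector of all sequence ids (singletons included).
#' @param hits a `pair_hits` table on those ids.
#' @param i minimum identity.
#' @param r minimum overlap.
#' @return a `cluster_set` with an `orientation` vector (`+`/`-` per id).
#' @export
single_linkage_cluster <- function(ids, hits, i = 0.35, r = 0.35) {
  if (anyDuplicated(ids)) stop("duplicated sequence ids")
  if (nrow(hits) && !all(c(hits$query, hits$subject) %in% ids))
    stop("hit references an unknown sequence id")
  q <- hits[hits$identity >= i & hits$overlap >= r & hits$query != hits$subject, ,
            drop = FALSE]
  from <- match(q$query, ids)
  to <- match(q$subject, ids)
  comp <- uf_components(length(ids), from, to)
  # orient by BFS from the lexicographically smallest member of each family
  orient <- rep("+", length(ids))
  if (nrow(q)) {
    adj <- split(seq_len(nrow(q) * 2),
                 c(from, to))
    edge_other <- c(to, from)
    edge_strand <- rep(q$strand, 2)
    for (fam in split(seq_along(ids), comp)) {
      if (length(fam) == 1) next
      start <- fam[order(ids[fam])[1]]
      seen <- start
      queue <- start
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (e in adj[[as.character(v)]]) {
          u <- edge_other[e]
          if (!(u %in% seen)) {
            orient[u] <- if (edge_strand[e] == "-")
              setdiff(c("+", "-"), orient[v]) else orient[v]
            seen <- c(seen, u)
            queue <- c(queue, u)
          }
        }
      }
    }
  }
  new_cluster_set(ids, comp, "single_linkage", stats::setNames(orient, ids))
}

# Global-alignment identity over the entire sequence length, checked on both
# strands; equal-length sequences reduce to 1 - hamming/L (the gapless global
# alignment is optimal for the identity-over-full-length criterion here).
global_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    fwd <- 1 - hamming_pair_cpp(a, b) / nchar(a)
    rev <- 1 - hamming_pair_cpp(a, revcomp(b)) / nchar(a)
  } else {
    ident <- function(x, y) {
      aln <- Biostrings::pairwiseAlignment(
        x, y, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2)
      Biostrings::nmatch(aln) / max(nchar(x), nchar(y))
    }
    fwd <- ident(a, b)
    rev <- ident(a, revcomp(b))
  }
  c(identity = max(fwd, rev), strand = if (fwd >= rev) "+" else "-")
}

#' Greedy centroid clustering
#'
#' Sequences are processed in `seed_order`; each sequence joins the first
#' existing centroid (in order of centroid creation) whose global-alignment
#' identity over the entire sequence length is at least `min_identity`, on
#' either strand, or founds a new centroid. Unlike single-linkage, the result
#' depends on the processing order, which is why a seed-shuffling replicate
#' mode is provided.
#'
#' @param seqs named character vector of sequences.
#' @param min_identity minimum identity over the full length.
#' @param seed_order optional integer permutation or character vector of ids
#'   giving the processing order (default: input order).
#' @return a `cluster_set`.
#' @export
greedy_centroid_cluster <- function(seqs, min_identity = 0.35, seed_order = NULL) {
  if (!length(seqs)) stop("need at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  ord <- if (is.null(seed_order)) seq_along(seqs)
         else if (is.character(seed_order)) match(seed_order, names(seqs))
         else as.integer(seed_order)
  if (anyNA(ord) || length(ord) != length(seqs) || anyDuplicated(ord))
    stop("seed_order must be a permutation of the input")
  centroids <- integer(0)            # indices into seqs
  membership <- integer(length(seqs))
  orient <- rep("+", length(seqs))
  equal_len <- length(unique(nchar(seqs))) == 1
  L <- nchar(seqs[[1]])
  for (k in ord) {
    joined <- FALSE
    if (length(centroids)) {
      if (equal_len) {
        idf <- 1 - drop(hamming_cross_cpp(seqs[[k]], seqs[centroids])) / L
        idr <- 1 - drop(hamming_cross_cpp(revcomp(seqs[[k]]), seqs[centroids])) / L
        best <- pmax(idf, idr)
        ci <- which(best >= min_identity)[1]
        if (!is.na(ci)) {
          membership[k] <- ci
          orient[k] <- if (idf[ci] >= idr[ci]) "+" else "-"
          joined <- TRUE
        }
      } else {
        for (ci in seq_along(centroids)) {
          gi <- global_identity(seqs[[centroids[ci]]], seqs[[k]])
          if (as.numeric(gi["identity"]) >= min_identity) {
            membership[k] <- ci
            orient[k] <- gi["strand"]
            joined <- TRUE
            break
          }
        }
      }
    }
    if (!joined) {
      centroids <- c(centroids, k)
      membership[k] <- length(centroids)
    }
  }
  new_cluster_set(names(seqs), membership, "greedy_centroid",
                  stats::setNames(orient, names(seqs)))
}

#' Remove clusters containing putative paralogs
#'
#' A cluster is removed when any specimen contributes two or more distinct
#' loci (sequences) to it: restriction sites in recently duplicated regions
#' produce exactly this signature and would confound phylogenetic analysis.
#'
#' @param clusters a `cluster_set`.
#' @param specimens named character vector: specimen label per sequence id.
#' @return list with `kept` and `removed` (lists of member-id vectors),
#'   `fraction_removed` (fraction of sequences lost) and
#'   `fraction_clusters_removed`.
#' @export
filter_paralogous_clusters <- function(clusters, specimens) {
  stopifnot(inherits(clusters, "cluster_set"))
  fams <- cluster_families(clusters)
  bad <- vapply(fams, function(f) anyDuplicated(specimens[f]) > 0, logical(1))
  list(kept = fams[!bad], removed = fams[bad],
       fraction_removed = if (length(clusters$ids))
         sum(lengths(fams[bad])) / length(clusters$ids) else 0,
       fraction_clusters_removed = if (length(fams)) mean(bad) else 0)
}

#' Orthology-recovery efficiency
#'
#' Over true ortholog groups with at least `min_species` distinct specimens
#' present in the input, the fraction whose members all sit together in one
#' cluster that contains no sequence from outside the group. Purity is part
#' of the definition: a group gathered together with even one paralog counts
#' as unrecovered, so the measure combines sensitivity and specificity.
#'
#' @param clusters a `cluster_set`.
#' @param truth named character vector: true group id per sequence id.
#' @param specimens named character vector: specimen label per sequence id.
#' @param min_species minimum number of distinct specimens for a group to
#'   enter the denominator (>= 2).
#' @return the efficiency fraction (NA when no group qualifies).
#' @export
clustering_efficiency <- function(clusters, truth, specimens, min_species = 4) {
  stopifnot(inherits(clusters, "cluster_set"), min_species >= 2)
  ids <- clusters$ids
  truth <- truth[ids]
  groups <- split(ids, truth)
  sizes <- vapply(groups, function(g) length(unique(specimens[g])), integer(1))
  groups <- groups[sizes >= min_species]
  if (!length(groups)) return(NA_real_)
  memb <- clusters$membership
  cl_sizes <- table(memb)
  ok <- vapply(groups, function(g) {
    cl <- unique(memb[match(g, ids)])
    length(cl) == 1 && cl_sizes[[as.character(cl)]] == length(g)
  }, logical(1))
  mean(ok)
}

#' Write a cluster set to TSV
#'
#' @param clusters a `cluster_set`.
#' @param path output file (columns cluster_id, member_id).
#' @export
write_clusters_tsv <- function(clusters, path) {
  utils::write.table(
    data.frame(cluster_id = clusters$membership, member_id = clusters$ids),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
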