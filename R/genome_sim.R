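#' Haploid genome with positional truth
#'
#' A haploid genome is a substitution-only evolving sequence together with a
#' truth map: for every position, the coordinate of the corresponding position
#' in the root ancestor (`coord`) and a duplication-lineage tag (`lineage`,
#' 0 for the original copy). Because the mutation model has no indels,
#' coordinates are preserved exactly by evolution and heterozygosity, and only
#' [insert_duplications()] creates new lineage tags. The truth map plays the
#' role that whole-genome alignments play for real genomes: it defines which
#' restriction sites and tags are orthologous or paralogous.
#'
#' @param taxon taxon label.
#' @param seq DNA sequence (single string over `{A,C,G,T}`).
#' @param coord integer vector of ancestral coordinates, one per position.
#' @param lineage integer vector of duplication-lineage tags, one per position.
#' @return an object of class `haploid_genome`.
#' @export
haploid_genome <- function(taxon, seq, coord = seq_len(nchar(seq)),
                           lineage = integer(nchar(seq))) {
  stopifnot(is.character(taxon), length(taxon) == 1,
            is.character(seq), length(seq) == 1, nchar(seq) > 0)
  if (length(coord) != nchar(seq) || length(lineage) != nchar(seq))
    stop("coord/lineage maps must have one entry per position")
  structure(list(taxon = taxon, seq = seq,
                 coord = as.integer(coord), lineage = as.integer(lineage)),
            class = "haploid_genome")
}

#' @export
print.haploid_genome <- function(x, ...) {
  cat(sprintf("<haploid_genome> taxon=%s length=%d (%d duplication lineage(s))\n",
              x$taxon, nchar(x$seq), length(unique(x$lineage))))
  invisible(x)
}

#' Generate a random ancestral genome
#'
#' Bases are drawn i.i.d.; G and C each have probability `gc/2`, A and T each
#' `(1-gc)/2`. The truth map of the ancestor is the identity.
#'
#' @param length genome length in bp (positive integer).
#' @param gc GC content, a fraction in `[0,1]`.
#' @param seed integer RNG seed.
#' @param taxon taxon label for the ancestor.
#' @return a [haploid_genome()].
#' @examples
#' g <- generate_ancestor(1000, 0.5, seed = 1)
#' @export
generate_ancestor <- function(length, gc = 0.5, seed, taxon = "ancestor") {
  if (!is.numeric(length) || length < 1) stop("length must be a positive integer")
  if (gc < 0 || gc > 1) stop("gc must be in [0,1]")
  length <- as.integer(length)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) # A C G T
  v <- with_seed(seed, sample.int(4L, length, replace = TRUE, prob = probs))
  haploid_genome(taxon, int_to_seq(v))
}

# Accept a phylo object or a newick string; validate for simulation use.
as_species_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object or newick string")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("duplicated taxon labels")
  tree
}

#' Evolve a genome along a species tree
#'
#' Applies a Jukes-Cantor-like substitution process independently on every
#' branch: on a branch of length `d` (expected substitutions/site) each site
#' is substituted with probability `(3/4)(1 - exp(-4d/3))`, uniformly to one
#' of the three other bases. The truth map is inherited unchanged, so
#' positions remain comparable across all descendants. Each branch draws from
#' its own named RNG substream, so results are independent of traversal order
#' and deterministic given `seed`.
#'
#' @param ancestor a [haploid_genome()] placed at the root.
#' @param tree a rooted tree (`phylo` or newick string) with branch lengths in
#'   expected substitutions per site.
#' @param seed integer RNG seed.
#' @return a named list of [haploid_genome()] objects, one per tip.
#' @export
evolve_along_tree <- function(ancestor, tree, seed) {
  stopifnot(inherits(ancestor, "haploid_genome"))
  tree <- as_species_tree(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- seq_to_int(ancestor$seq)
  # cladewise order guarantees parents are simulated before their children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    d <- ord$edge.length[e]
    lab <- if (child <= n_tip) tree$tip.label[child] else paste0("node", child)
    seqs[[child]] <- with_seed(substream_seed(seed, paste0("evolve:", lab)),
                               mutate_sites(seqs[[par]], jc_sub_prob(d)))
  }
  out <- lapply(seq_len(n_tip), function(i)
    haploid_genome(tree$tip.label[i], int_to_seq(seqs[[i]]),
                   ancestor$coord, ancestor$lineage))
  names(out) <- tree$tip.label
  out
}

#' Insert segmental duplications
#'
#' Copies `n_dup` segments of length `dup_len` to uniformly chosen positions
#' that do not overlap their own source, overwriting the target sequence (the
#' genome length is unchanged, keeping positional truth exact). Each copy is
#' mutated at per-site probability `post_dup_divergence` and its truth map
#' keeps the source ancestral coordinates but receives a fresh lineage tag,
#' so downstream truth labels the copies as paralogous.
#'
#' @param genome a [haploid_genome()].
#' @param n_dup number of duplications (0 leaves the genome untouched).
#' @param dup_len duplicated segment length in bp.
#' @param post_dup_divergence per-site substitution probability applied to
#'   each copy after insertion.
#' @param seed integer RNG seed.
#' @param max_fraction maximum total duplicated fraction of the genome.
#' @return a [haploid_genome()] with updated sequence and truth map.
#' @export
insert_duplications <- function(genome, n_dup, dup_len, post_dup_divergence = 0,
                                seed, max_fraction = 0.2) {
  stopifnot(inherits(genome, "haploid_genome"))
  if (n_dup == 0) return(genome)
  L <- nchar(genome$seq)
  if (dup_len >= L) stop("dup_len must be smaller than the genome length")
  if (n_dup * dup_len > max_fraction * L)
    stop("total duplicated length exceeds max_fraction of the genome")
  v <- seq_to_int(genome$seq)
  coord <- genome$coord
  lineage <- genome$lineage
  next_tag <- max(lineage) + 1L
  with_seed(substream_seed(seed, "duplications"), {
    for (k in seq_len(n_dup)) {
      src <- sample.int(L - dup_len + 1L, 1L)
      repeat {
        tgt <- sample.int(L - dup_len + 1L, 1L)
        if (tgt + dup_len - 1L < src || tgt > src + dup_len - 1L) break
      }
      seg <- mutate_sites(v[src:(src + dup_len - 1L)], post_dup_divergence)
      idx <- tgt:(tgt + dup_len - 1L)
      v[idx] <- seg
      coord[idx] <- genome$coord[src:(src + dup_len - 1L)]
      lineage[idx] <- next_tag
      next_tag <- next_tag + 1L
    }
  })
  haploid_genome(genome$taxon, int_to_seq(v), coord, lineage)
}

#' Diploidize a haploid genome
#'
#' Creates the second haplotype by mutating each site of the first
#' independently with probability `h` to one of the three other bases, so the
#' realized allele distance is `h` up to binomial error. The truth map is
#' shared between the two haplotypes.
#'
#' @param genome a [haploid_genome()] used as haplotype a.
#' @param h target per-site heterozygosity, in `[0, 0.2]`.
#' @param seed integer RNG seed.
#' @return an object of class `diploid_genome` with elements `specimen`, `a`,
#'   `b` (both [haploid_genome()]) and `h`.
#' @export
diploidize <- function(genome, h, seed) {
  stopifnot(inherits(genome, "haploid_genome"))
  if (h < 0 || h > 0.2) stop("h must be in [0, 0.2]")
  vb <- with_seed(substream_seed(seed, paste0("diploid:", genome$taxon)),
                  mutate_sites(seq_to_int(genome$seq), h))
  b <- haploid_genome(genome$taxon, int_to_seq(vb), genome$coord, genome$lineage)
  structure(list(specimen = genome$taxon, a = genome, b = b, h = h),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("<diploid_genome> specimen=%s length=%d h=%g\n",
              x$specimen, nchar(x$a$seq), x$h))
  invisible(x)
}

#' Realized p-distance between two equal-length sequences
#'
#' @param a,b DNA strings of equal length (or [haploid_genome()] objects).
#' @return proportion of differing positions.
#' @export
p_distance <- function(a, b) {
  if (inherits(a, "haploid_genome")) a <- a$seq
  if (inherits(b, "haploid_genome")) b <- b$seq
  hamming_pair_cpp(a, b) / nchar(a)
}

#' Write specimen genomes to FASTA
#'
#' One file per specimen; diploid specimens get two records with `_a`/`_b`
#' suffixes.
#'
#' @param genomes list of [haploid_genome()] or `diploid_genome` objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_genomes_fasta <- function(genomes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (g in genomes) {
    if (inherits(g, "diploid_genome")) {
      ss <- Biostrings::DNAStringSet(c(g$a$seq, g$b$seq))
      names(ss) <- paste0(g$specimen, c("_a", "_b"))
      path <- file.path(dir, paste0(g$specimen, ".fasta"))
    } else {
      ss <- Biostrings::DNAStringSet(g$seq)
      names(ss) <- g$taxon
      path <- file.path(dir, paste0(g$taxon, ".fasta"))
    }
    Biostrings::writeXStringSet(ss, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a truth map to TSV
#'
#' Columns: position (1-based), ancestral_coord, lineage_tag.
#'
#' @param genome a [haploid_genome()].
#' @param path output file.
#' @export
write_truth_map <- function(genome, path) {
  stopifnot(inherits(genome, "haploid_genome"))
  utils::write.table(
    data.frame(position = seq_along(genome$coord),
               ancestral_coord = genome$coord,
               lineage_tag = genome$lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
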