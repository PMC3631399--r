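#' Find restriction sites
#'
#' Reports every exact occurrence of the recognition motif, sorted by
#' position (1-based, leftmost motif base); overlapping occurrences are all
#' reported. The default motif is the Sbf1 recognition site `CCTGCAGG`, an
#' 8-bp GC-rich palindrome, so a single-strand scan suffices; for a
#' non-palindromic motif, occurrences of its reverse complement are reported
#' as well (with `strand = "-"`).
#'
#' @param x a [haploid_genome()] or a DNA string.
#' @param motif recognition motif over `{A,C,G,T}`.
#' @return a data frame with columns `position`, `ancestral_coord`,
#'   `lineage`, `strand`, with the motif stored in `attr(, "motif")`.
#' @examples
#' find_sites("AACCTGCAGGTT")$position # 3 (1-based)
#' @export
find_sites <- function(x, motif = "CCTGCAGG") {
  if (!grepl("^[ACGT]+$", motif)) stop("motif contains characters outside {A,C,G,T}")
  if (inherits(x, "haploid_genome")) {
    seq <- x$seq; coord <- x$coord; lineage <- x$lineage
  } else {
    seq <- x; coord <- seq_len(nchar(seq)); lineage <- integer(nchar(seq))
  }
  subject <- Biostrings::DNAString(seq)
  pos <- Biostrings::start(Biostrings::matchPattern(motif, subject))
  strand <- rep("+", length(pos))
  rc <- revcomp(motif)
  if (!identical(rc, motif)) {
    pos2 <- Biostrings::start(Biostrings::matchPattern(rc, subject))
    pos2 <- setdiff(pos2, pos)
    pos <- c(pos, pos2)
    strand <- c(strand, rep("-", length(pos2)))
  }
  o <- order(pos)
  out <- data.frame(position = pos[o],
                    ancestral_coord = coord[pos[o]],
                    lineage = lineage[pos[o]],
                    strand = strand[o],
                    stringsAsFactors = FALSE)
  attr(out, "motif") <- motif
  out
}

# Locus identifier shared across specimens: ancestral coordinate + lineage
# tag of the motif start, plus the side of the site.
locus_id <- function(coord, lineage, side) sprintf("%d.%d:%s", coord, lineage, side)

#' Extract RAD tags flanking restriction sites
#'
#' For each site, up to two fixed-length tags are emitted: the 3' tag is the
#' `tag_len` bases immediately right of the motif; the 5' tag is the reverse
#' complement of the `tag_len` bases immediately left of the motif, so both
#' tags read away from the cut site, as sequencing reads do. Sites closer
#' than `tag_len` to a sequence end yield only the feasible side; truncated
#' tags are never emitted (real reads have fixed length).
#'
#' @param genome a [haploid_genome()].
#' @param sites a site table from [find_sites()] (its `motif` attribute
#'   supplies the motif width).
#' @param tag_len tag length in bp (>= 1).
#' @param allele allele label recorded on the tags (`"a"` or `"b"`).
#' @return a data frame with columns `specimen`, `site_coord`, `lineage`,
#'   `side`, `allele`, `locus`, `seq`, `position`.
#' @export
extract_tags <- function(genome, sites, tag_len, allele = "a") {
  stopifnot(inherits(genome, "haploid_genome"))
  if (tag_len < 1) stop("tag_len must be >= 1")
  motif <- attr(sites, "motif")
  if (is.null(motif)) stop("sites table lacks its motif attribute; use find_sites()")
  ml <- nchar(motif)
  L <- nchar(genome$seq)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    if (pos - tag_len >= 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = genome$taxon, site_coord = sites$ancestral_coord[i],
        lineage = sites$lineage[i], side = "5prime", allele = allele,
        locus = locus_id(sites$ancestral_coord[i], sites$lineage[i], "5prime"),
        seq = revcomp(substr(genome$seq, pos - tag_len, pos - 1L)),
        position = pos, stringsAsFactors = FALSE)
    }
    if (pos + ml - 1L + tag_len <= L) {
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = genome$taxon, site_coord = sites$ancestral_coord[i],
        lineage = sites$lineage[i], side = "3prime", allele = allele,
        locus = locus_id(sites$ancestral_coord[i], sites$lineage[i], "3prime"),
        seq = substr(genome$seq, pos + ml, pos + ml - 1L + tag_len),
        position = pos, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(specimen = character(0), site_coord = integer(0),
                      lineage = integer(0), side = character(0),
                      allele = character(0), locus = character(0),
                      seq = character(0), position = integer(0)))
  do.call(rbind, rows)
}

#' Digest a diploid specimen
#'
#' Finds restriction sites and extracts tags independently on the two
#' haplotypes (a site lost by mutation on one haplotype yields tags only from
#' the other, i.e. hemizygous loci arise naturally).
#'
#' @param dg a `diploid_genome` from [diploidize()].
#' @param motif recognition motif.
#' @param tag_len tag length in bp.
#' @return the combined tag table (see [extract_tags()]).
#' @export
digest_diploid <- function(dg, motif = "CCTGCAGG", tag_len = 85) {
  stopifnot(inherits(dg, "diploid_genome"))
  rbind(extract_tags(dg$a, find_sites(dg$a, motif), tag_len, allele = "a"),
        extract_tags(dg$b, find_sites(dg$b, motif), tag_len, allele = "b"))
}

#' Restriction-site conservation versus divergence
#'
#' For every pair of genomes sharing a truth map, reports the fraction of the
#' reference genome's restriction sites (the first genome of the pair) that
#' are present, at the same ancestral coordinate and lineage tag, in the
#' other genome. Divergence is reported as the realized whole-genome
#' p-distance; in a neutral simulation this stands in for divergence measured
#' at fourfold degenerate sites in real genomes.
#'
#' @param genomes named list of [haploid_genome()] objects descended from a
#'   common ancestor (equal lengths).
#' @param motif recognition motif.
#' @return data frame with one row per unordered pair: `taxon_a` (reference),
#'   `taxon_b`, `divergence`, `n_sites_ref`, `n_conserved`, `fraction`.
#' @export
conservation_curve <- function(genomes, motif = "CCTGCAGG") {
  if (length(genomes) < 2) stop("need at least two genomes")
  lens <- vapply(genomes, function(g) nchar(g$seq), integer(1))
  if (length(unique(lens)) != 1) stop("genomes must descend from one ancestor (equal lengths)")
  keys <- lapply(genomes, function(g) {
    s <- find_sites(g, motif)
    paste(s$ancestral_coord, s$lineage, sep = ".")
  })
  nm <- names(genomes)
  rows <- list()
  for (i in seq_along(genomes)[-length(genomes)]) {
    for (j in (i + 1):length(genomes)) {
      n_ref <- length(keys[[i]])
      n_cons <- length(intersect(keys[[i]], keys[[j]]))
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = nm[i], taxon_b = nm[j],
        divergence = p_distance(genomes[[i]], genomes[[j]]),
        n_sites_ref = n_ref, n_conserved = n_cons,
        fraction = if (n_ref > 0) n_cons / n_ref else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write RAD tags to FASTA
#'
#' Headers encode `specimen|locus|side|allele`.
#'
#' @param tags a tag table from [extract_tags()] or [digest_diploid()].
#' @param path output file.
#' @export
write_tags_fasta <- function(tags, path) {
  ss <- Biostrings::DNAStringSet(tags$seq)
  names(ss) <- paste(tags$specimen, tags$locus, tags$side, tags$allele, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
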