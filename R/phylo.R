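#' Align one homolog family
#'
#' The simulator is indel-free and all tags are anchored at the restriction
#' site, so the alignment is positional: column k is position k of every
#' member (members must already be oriented to the same strand, see
#' [single_linkage_cluster()] orientations). Members shorter than the widest
#' member (e.g. 35-bp tags mixed with 85-bp tags) are right-padded with gaps.
#'
#' @param members named character vector (names = specimen labels).
#' @param id family identifier.
#' @return object of class `family_alignment`: list with `id`, `taxa` and
#'   `matrix` (character matrix, one row per member, one column per site).
#' @export
align_family <- function(members, id = "family") {
  if (!length(members)) stop("empty family")
  if (is.null(names(members))) stop("members must be named by specimen")
  width <- max(nchar(members))
  padded <- paste0(members, strrep("-", width - nchar(members)))
  m <- do.call(rbind, lapply(padded, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
  rownames(m) <- names(members)
  structure(list(id = id, taxa = names(members), matrix = m, width = width),
            class = "family_alignment")
}

#' Concatenate family alignments into a supermatrix
#'
#' Families with fewer than `min_taxa` distinct specimens are excluded
#' (alignments with too few species carry no usable topological information);
#' the rest are concatenated in lexicographic order of family id, and taxa
#' missing from a family are filled with gap characters across that family's
#' span. Per-taxon gap fractions are reported.
#'
#' @param families list of `family_alignment` objects (paralog-filtered, at
#'   most one row per specimen each).
#' @param min_taxa minimum number of distinct specimens per family.
#' @return object of class `supermatrix`: list with `taxa`, `matrix`
#'   (taxa x width character matrix over `{A,C,G,T,-}`), `spans` (data frame
#'   `family`, `start`, `end`) and `gap_fraction` (named numeric).
#' @export
build_supermatrix <- function(families, min_taxa = 4) {
  keep <- Filter(function(f) length(unique(f$taxa)) >= min_taxa, families)
  if (!length(keep)) stop("no family has at least min_taxa specimens")
  keep <- keep[order(vapply(keep, `[[`, character(1), "id"))]
  taxa <- sort(unique(unlist(lapply(keep, `[[`, "taxa"))))
  width <- sum(vapply(keep, `[[`, numeric(1), "width"))
  m <- matrix("-", nrow = length(taxa), ncol = width,
              dimnames = list(taxa, NULL))
  spans <- data.frame(family = character(0), start = integer(0), end = integer(0))
  at <- 1L
  for (f in keep) {
    idx <- at:(at + f$width - 1L)
    m[f$taxa, idx] <- f$matrix
    spans <- rbind(spans, data.frame(family = f$id, start = at,
                                     end = at + f$width - 1L))
    at <- at + f$width
  }
  structure(list(taxa = taxa, matrix = m, spans = spans,
                 gap_fraction = rowMeans(m == "-")),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d families, gap fraction %.1f-%.1f%%\n",
              length(x$taxa), ncol(x$matrix), nrow(x$spans),
              100 * min(x$gap_fraction), 100 * max(x$gap_fraction)))
  invisible(x)
}

# Pairwise distances on a character matrix with pairwise deletion.
dist_from_char_matrix <- function(m, correction = c("jc", "p")) {
  correction <- match.arg(correction)
  taxa <- rownames(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop(sprintf("taxa %s and %s share no ungapped column", taxa[i], taxa[j]))
      p <- mean(m[i, ok] != m[j, ok])
      v <- if (correction == "p") p else {
        if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  d
}

#' Pairwise distance matrix from a supermatrix
#'
#' Pairwise deletion: columns gapped in either row are ignored for that pair.
#' `correction = "p"` gives the raw mismatch fraction, `"jc"` the
#' Jukes-Cantor distance `-(3/4) ln(1 - 4p/3)` (reported as `NaN` when `p >=
#' 0.75`, where the correction is undefined). A taxon pair sharing no
#' ungapped column is an error: imputing such distances silently would
#' distort the tree.
#'
#' @param x a `supermatrix` (or a character matrix with taxa as rownames).
#' @param correction `"jc"` (default) or `"p"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, correction = c("jc", "p")) {
  m <- if (inherits(x, "supermatrix")) x$matrix else x
  dist_from_char_matrix(m, match.arg(correction))
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via \pkg{ape}) on a symmetric distance matrix;
#' recovers the generating topology (and branch lengths) exactly when the
#' input is additive.
#'
#' @param d symmetric non-negative distance matrix over >= 3 taxa.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains undefined entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for the supermatrix tree
#'
#' Site (column) bootstrap on the concatenated alignment: columns are
#' resampled with replacement, a neighbor-joining tree is built on each
#' replicate, and the support of every internal edge of the full-data tree is
#' the percentage of replicates whose tree contains the same bipartition.
#'
#' @param x a `supermatrix`.
#' @param reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @param correction distance correction passed to [distance_matrix()].
#' @return object of class `supported_tree`: list with `tree` (a `phylo`
#'   whose node labels hold the supports), `supports` (numeric, one per
#'   non-root internal node, in `[0,100]`) and `reps`.
#' @export
bootstrap_support <- function(x, reps = 100, seed = 1, correction = "jc") {
  stopifnot(inherits(x, "supermatrix"), reps >= 1)
  main <- nj_tree(distance_matrix(x, correction))
  w <- ncol(x$matrix)
  boots <- with_seed(seed, lapply(seq_len(reps), function(b) {
    cols <- sample.int(w, w, replace = TRUE)
    nj_tree(dist_from_char_matrix(x$matrix[, cols, drop = FALSE], correction))
  }))
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / reps)
  tree <- main
  tree$node.label <- as.character(support)
  # node 1 in the phylo node numbering is the (arbitrary) root of the
  # unrooted representation; its "bipartition" is trivial
  structure(list(tree = tree, supports = support[-1], reps = reps),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("<supported_tree> %d taxa, %d internal supports (min %s), %d bootstrap replicates\n",
              length(x$tree$tip.label), length(x$supports),
              if (length(x$supports)) min(x$supports) else "-", x$reps))
  invisible(x)
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of the two unrooted trees;
#' 0 means identical topologies.
#'
#' @param tree_a,tree_b `phylo` trees over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b)))
}

#' Informative loci per internal node
#'
#' For each internal node of a rooted tree (excluding the root, which has no
#' outgroup), counts the families containing at least one taxon from each
#' child clade of the node and at least one taxon outside the node's clade:
#' these are the loci able to inform that bifurcation.
#'
#' @param families list of `family_alignment` objects (or character vectors
#'   of taxa).
#' @param tree a rooted `phylo` tree.
#' @return data frame with `node` (phylo node number) and `n_informative`.
#' @export
informative_loci_per_node <- function(families, tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted for node orientation")
  fam_taxa <- lapply(families, function(f)
    if (inherits(f, "family_alignment")) unique(f$taxa) else unique(f))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  nodes <- setdiff(unique(tree$edge[, 1]), root)
  desc <- phangorn::Descendants(tree, type = "tips")
  rows <- lapply(nodes, function(nd) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    clades <- lapply(kids, function(k)
      tree$tip.label[desc[[k]]])
    inside <- tree$tip.label[desc[[nd]]]
    outside <- setdiff(tree$tip.label, inside)
    n <- sum(vapply(fam_taxa, function(ft)
      all(vapply(clades, function(cl) any(ft %in% cl), logical(1))) &&
        any(ft %in% outside), logical(1)))
    data.frame(node = nd, n_informative = n)
  })
  do.call(rbind, rows)
}

#' Export a supermatrix
#'
#' @param x a `supermatrix`.
#' @param path output file.
#' @export
write_supermatrix_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(apply(x$matrix, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(x$taxa), ncol(x$matrix)), con)
  for (t in x$taxa)
    writeLines(paste(t, paste(x$matrix[t, ], collapse = "")), con)
  invisible(path)
}
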