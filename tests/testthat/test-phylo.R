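test_that("family alignment is positional with right-padding", {
  a <- random_dna(85, seed = 60)
  fa <- align_family(c(sp1 = a, sp2 = a), id = "f1")
  expect_equal(fa$width, 85)
  expect_true(all(fa$matrix[1, ] == fa$matrix[2, ]))

  b <- mutate_at(a, c(3, 10, 40, 80))
  fa2 <- align_family(c(sp1 = a, sp2 = b))
  expect_equal(sum(fa2$matrix[1, ] != fa2$matrix[2, ]), 4)

  short <- substr(a, 1, 35)
  fa3 <- align_family(c(sp1 = a, sp2 = short))
  expect_equal(fa3$width, 85)
  expect_equal(sum(fa3$matrix[2, ] == "-"), 50)
  expect_error(align_family(character(0)), "empty")
})

test_that("supermatrix concatenates qualifying families and tracks gaps", {
  a <- random_dna(85, seed = 61)
  mk <- function(taxa, id) align_family(stats::setNames(rep(a, length(taxa)), taxa), id)
  fams <- list(mk(c("t1", "t2", "t3", "t4"), "f1"),
               mk(c("t1", "t2", "t3"), "f2"),      # too few taxa
               mk(c("t1", "t2", "t3", "t5"), "f3"))
  sm <- build_supermatrix(fams, min_taxa = 4)
  expect_equal(ncol(sm$matrix), 170)
  expect_equal(sort(sm$taxa), c("t1", "t2", "t3", "t4", "t5"))
  expect_equal(unname(sm$gap_fraction["t1"]), 0)
  expect_equal(unname(sm$gap_fraction["t4"]), 0.5)
  expect_error(build_supermatrix(fams, min_taxa = 6), "min_taxa")
})

test_that("pairwise distances use pairwise deletion and the JC correction", {
  m <- rbind(x = c("A", "A", "A", "A"), y = c("A", "A", "A", "T"))
  expect_equal(distance_matrix(m, "p")["x", "y"], 0.25)
  expect_equal(distance_matrix(m, "jc")["x", "y"], -0.75 * log(1 - 1 / 3),
               tolerance = 1e-12)
  expect_equal(unname(distance_matrix(rbind(x = c("A", "C"), y = c("A", "C")),
                                      "jc")["x", "y"]), 0)

  gapped <- rbind(x = c("A", "-", "T"), y = c("-", "C", "T"), z = c("A", "C", "A"))
  expect_equal(unname(distance_matrix(gapped, "p")["x", "y"]), 0)
  bad <- rbind(x = c("A", "-"), y = c("-", "C"))
  expect_error(distance_matrix(bad), "no ungapped")

  # oracle: matches ape's JC distances on a gapless random alignment
  set.seed(62)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 400, replace = TRUE), nrow = 5,
                dimnames = list(paste0("t", 1:5), NULL))
  mat[2, 1:300] <- mat[1, 1:300]
  ours <- distance_matrix(mat, "jc")
  apes <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "JC69",
                                  pairwise.deletion = TRUE))
  expect_equal(ours[rownames(apes), colnames(apes)], apes, tolerance = 1e-8)
})

test_that("neighbor joining recovers additive trees exactly", {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4));")
  expect_equal(rf_distance(tr, truth), 0)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))

  # 3 taxa: unique star with exact branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  expect_equal(sort(tr3$edge.length), c(1, 2, 3))

  # ultrametric 8-taxon matrix: topology equals the generating tree
  set.seed(63)
  g8 <- ape::rcoal(8)
  expect_equal(rf_distance(nj_tree(ape::cophenetic.phylo(g8)), g8), 0)

  asym <- d; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

test_that("Robinson-Foulds distance counts one-sided bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  bin5 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  expect_equal(rf_distance(star, bin5), 2)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "leaf sets")
})

test_that("bootstrap supports reflect signal strength", {
  fams <- simulate_tag_families(25, balanced12_tree(), seed = 64)
  aln <- lapply(split(seq_along(fams$seqs), fams$truth), function(idx)
    align_family(stats::setNames(fams$seqs[idx], fams$specimens[idx]),
                 id = fams$truth[idx[1]]))
  sm <- build_supermatrix(aln, min_taxa = 4)

  one <- bootstrap_support(sm, reps = 1, seed = 1)
  expect_true(all(one$supports %in% c(0, 100)))

  st <- bootstrap_support(sm, reps = 100, seed = 2)
  expect_equal(rf_distance(st$tree, balanced12_tree()), 0)
  expect_true(all(st$supports >= 95))

  # negative control: permuting columns within every row destroys the signal
  perm <- sm
  set.seed(65)
  for (i in seq_len(nrow(perm$matrix)))
    perm$matrix[i, ] <- perm$matrix[i, sample(ncol(perm$matrix))]
  stp <- bootstrap_support(perm, reps = 100, seed = 3, correction = "p")
  expect_lt(min(stp$supports), 95)
})

test_that("informative locus counts require both child clades and an outgroup", {
  tree <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  fam_all <- align_family(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"), "f1")
  fam_one_side <- align_family(c(a = "ACGT", b = "ACGT"), "f2")
  counts <- informative_loci_per_node(list(fam_all, fam_one_side), tree)
  # every non-root internal node sees the complete family
  expect_true(all(counts$n_informative >= 1))
  # the a/b-only family informs no node (no outgroup at (a,b); one-sided above)
  counts2 <- informative_loci_per_node(list(fam_one_side), tree)
  expect_true(all(counts2$n_informative == 0))
  expect_error(informative_loci_per_node(list(fam_all),
                                         ape::unroot(tree)), "rooted")
})
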