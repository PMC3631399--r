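test_that("ancestral genome has the requested composition and is reproducible", {
  g <- generate_ancestor(1000, 0.5, seed = 1)
  expect_s3_class(g, "haploid_genome")
  expect_equal(nchar(g$seq), 1000)
  expect_identical(g$coord, 1:1000)
  freq <- table(strsplit(g$seq, "")[[1]]) / 1000
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 1000)))

  at_only <- generate_ancestor(50, 0, seed = 2)
  expect_true(grepl("^[AT]+$", at_only$seq))

  expect_identical(generate_ancestor(500, 0.4, seed = 7)$seq,
                   generate_ancestor(500, 0.4, seed = 7)$seq)
  expect_error(generate_ancestor(0, 0.5, seed = 1), "positive")
  expect_error(generate_ancestor(10, 1.5, seed = 1), "gc")
})

test_that("evolution matches the Jukes-Cantor expected p-distance", {
  L <- 1e5
  anc <- generate_ancestor(L, 0.5, seed = 3)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  leaves <- evolve_along_tree(anc, tr, seed = 4)

  p_exp <- jc_expected_pdist(0.1)
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_distance(anc, leaves$a) - p_exp), 4 * se)

  # two sisters at depth d each: pairwise path 2d
  p2 <- jc_expected_pdist(0.2)
  se2 <- sqrt(p2 * (1 - p2) / L)
  expect_lt(abs(p_distance(leaves$a, leaves$b) - p2), 4 * se2)

  # zero branch leaves the sequence untouched; coordinates always inherited
  z <- evolve_along_tree(anc, ape::read.tree(text = "(x:0,y:0.05);"), seed = 5)
  expect_identical(z$x$seq, anc$seq)
  expect_identical(z$y$coord, anc$coord)
  expect_identical(z$y$lineage, anc$lineage)

  expect_error(evolve_along_tree(anc, ape::read.tree(text = "(a:-0.1,b:0.1);"),
                                 seed = 1), "negative")
  expect_identical(evolve_along_tree(anc, tr, seed = 9)$a$seq,
                   evolve_along_tree(anc, tr, seed = 9)$a$seq)
})

test_that("diploidization realizes the target heterozygosity", {
  L <- 1e5
  g <- generate_ancestor(L, 0.5, seed = 6)
  d <- diploidize(g, 0.05, seed = 7)
  se <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(p_distance(d$a, d$b) - 0.05), 4 * se)
  expect_identical(d$b$coord, g$coord)

  d0 <- diploidize(g, 0, seed = 8)
  expect_identical(d0$a$seq, d0$b$seq)
  expect_error(diploidize(g, 1, seed = 1), "h must be")
})

test_that("duplications copy truth coordinates under a fresh lineage tag", {
  g <- generate_ancestor(20000, 0.5, seed = 10)
  expect_identical(insert_duplications(g, 0, 100, 0, seed = 1), g)

  dup <- insert_duplications(g, 1, 2000, 0, seed = 11)
  new_tag <- setdiff(unique(dup$lineage), 0L)
  expect_length(new_tag, 1)
  idx <- which(dup$lineage == new_tag)
  expect_length(idx, 2000)
  # the copy carries its source's ancestral coordinates and sequence (divergence 0)
  src <- dup$coord[idx]
  expect_identical(substr(dup$seq, idx[1], idx[length(idx)]),
                   substr(g$seq, src[1], src[length(src)]))

  # a duplicated restriction site is counted twice, same coord, new lineage
  motif <- "CCTGCAGG"
  site_seq <- paste0(random_dna(500, seed = 1), motif, random_dna(500))
  gs <- haploid_genome("t", site_seq)
  repeat {
    dups <- insert_duplications(gs, 1, 200, 0, seed = sample.int(1e6, 1))
    s <- find_sites(dups, motif)
    if (nrow(s) == 2) break
  }
  expect_equal(s$ancestral_coord[1], s$ancestral_coord[2])
  expect_false(s$lineage[1] == s$lineage[2])

  # post-duplication divergence oracle
  g2 <- generate_ancestor(50000, 0.5, seed = 12)
  d2 <- insert_duplications(g2, 1, 5000, 0.15, seed = 13)
  idx2 <- which(d2$lineage != 0L)
  copy <- substr(d2$seq, idx2[1], idx2[length(idx2)])
  src2 <- substr(g2$seq, d2$coord[idx2[1]], d2$coord[idx2[length(idx2)]])
  frac <- hamming(copy, src2) / 5000
  expect_lt(abs(frac - 0.15), 4 * sqrt(0.15 * 0.85 / 5000))

  expect_error(insert_duplications(g, 10, 1000, 0, seed = 1), "max_fraction")
})
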