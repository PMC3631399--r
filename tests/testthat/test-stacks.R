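test_that("stacks form from strictly identical reads only", {
  s1 <- random_dna(85, seed = 40)
  s2 <- mutate_at(s1, 1:3)
  x <- build_stacks(c(s1, s1, s1, s2), m = 2)
  expect_equal(nrow(x$stacks), 1)
  expect_equal(x$stacks$depth, 3)
  expect_length(x$secondary, 1)

  # all-unique reads at m=2: the locus is unrecoverable
  uniq <- vapply(1:5, function(i) mutate_at(s1, i), character(1))
  x2 <- build_stacks(uniq, m = 2)
  expect_equal(nrow(x2$stacks), 0)
  expect_length(x2$secondary, 5)

  # m=1 promotes every distinct sequence
  x3 <- build_stacks(uniq, m = 1)
  expect_equal(nrow(x3$stacks), 5)
  expect_length(x3$secondary, 0)

  expect_error(build_stacks(c("ACGT", "ACG"), 2), "mixed")
})

test_that("stack merging is single linkage under the mismatch cap", {
  base <- random_dna(85, seed = 41)
  near <- mutate_at(base, 1:4)     # hamming 4
  far <- mutate_at(base, 1:14)     # hamming 14
  mk <- function(seqs) build_stacks(rep(seqs, each = 2), m = 2)

  expect_length(merge_stacks(mk(c(base, near)), M = 13)$loci, 1)
  expect_length(merge_stacks(mk(c(base, far)), M = 13)$loci, 2)
  expect_length(merge_stacks(mk(c(base, mutate_at(base, 1:13))), M = 13)$loci, 1)

  # chain A-B = 10, B-C = 10, A-C = 20: one locus by transitivity
  a <- base; b <- mutate_at(base, 1:10); c3 <- mutate_at(base, 1:20)
  expect_length(merge_stacks(mk(c(a, b, c3)), M = 13)$loci, 1)
})

test_that("merging equals brute-force transitive closure on random instances", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(2:60, 1)
    M <- sample(0:20, 1)
    base <- random_dna(60)
    seqs <- vapply(seq_len(n), function(i)
      mutate_at(base, sample(60, sample(0:25, 1))), character(1))
    seqs <- unique(seqs)
    x <- build_stacks(rep(seqs, each = 2), m = 2)
    got <- merge_stacks(x, M)
    d <- outer(seq_along(x$stacks$seq), seq_along(x$stacks$seq),
               Vectorize(function(i, j) hamming(x$stacks$seq[i], x$stacks$seq[j])))
    e <- which(d <= M & upper.tri(d), arr.ind = TRUE)
    want <- bf_components(nrow(x$stacks), e[, 1], e[, 2])
    memb <- integer(nrow(x$stacks))
    for (k in seq_along(got$loci)) memb[got$loci[[k]]$stacks] <- k
    expect_identical(canon_partition(memb), canon_partition(want))
  }
})

test_that("consensus is a depth-weighted majority with fixed tie order", {
  expect_equal(call_consensus("ACGT"), "ACGT")
  expect_equal(call_consensus(c("AAAA", "CAAA"), depths = c(3, 1)), "AAAA")
  expect_equal(call_consensus(c("CAAA", "GAAA"), depths = c(2, 2)), "CAAA")
  expect_equal(call_consensus(c("TAAA", "GAAA"), depths = c(1, 1)), "GAAA")
})

test_that("secondary reads attach to the unique nearest locus within N_mm", {
  cons1 <- random_dna(85, seed = 43)
  cons2 <- mutate_at(cons1, 1:40)
  reads <- c(rep(cons1, 3), rep(cons2, 3),
             mutate_at(cons1, 10:18),   # 9 mismatches from locus 1
             mutate_at(cons1, 10:19),   # 10 mismatches
             mutate_at(cons1, 21:60))   # equidistant (40 and 40+...) check below
  ls <- merge_stacks(build_stacks(reads, m = 2), M = 13)
  expect_length(ls$loci, 2)
  ls <- attach_secondary(ls, N_mm = 9)
  att <- unlist(lapply(ls$loci, `[[`, "attached"))
  expect_length(att, 1)
  expect_equal(ls$reads[att], mutate_at(cons1, 10:18))

  # an exactly equidistant read stays unattached
  eq <- c(rep("AAAAAAAA", 2), rep("TTTTTTTT", 2), "AAAATTTT")
  ls2 <- attach_secondary(merge_stacks(build_stacks(eq, 2), M = 2), N_mm = 8)
  expect_length(unlist(lapply(ls2$loci, `[[`, "attached")), 0)
  expect_equal(ls2$unattached, 5L)

  # read conservation: stacks + attached + unattached = all reads
  n_stack_reads <- sum(vapply(ls$loci, function(l) length(l$read_idx), 1L))
  expect_equal(n_stack_reads + length(att) + length(ls$unattached), length(reads))
})

test_that("noise-free assembly recovers every locus exactly", {
  set.seed(44)
  tags <- data.frame(specimen = "s", locus = sprintf("L%03d", 1:200),
                     allele = "a",
                     seq = vapply(1:200, function(i) random_dna(85), character(1)))
  reads <- simulate_reads(tags, 10, 0, seed = 45, allele_share = 1)
  ls <- assemble_loci(reads$seq, stack_params())
  met <- stacks_metrics(ls, reads$locus)
  expect_equal(met$split_rate, 0)
  expect_equal(met$paralog_merge_rate, 0)
  expect_true(all(vapply(ls$loci, `[[`, character(1), "consensus") %in% tags$seq))
})

test_that("recovery improves with coverage and degrades with error rate", {
  rec <- function(lam, e) simulate_locus_recovery(
    1500, mean_coverage = lam, error_rate = e, seed = 46)$recovery_rate
  expect_gte(rec(15, 0.01), rec(5, 0.01))
  expect_gte(rec(10, 0), rec(10, 0.05))
})
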