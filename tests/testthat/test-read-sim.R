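test_that("coverage and pool-size calculators evaluate the design formula", {
  # one Illumina lane spread over 200 genomes of ~2308 sites
  expect_equal(coverage_per_locus(1.5e8, 200, 2308)$C,
               1.5e8 / (200 * 2 * 2308), tolerance = 1e-12)
  expect_equal(coverage_per_locus(10, 1, 1)$C, 5)
  expect_equal(coverage_per_locus(1e6, 100, 50)$C,
               2 * coverage_per_locus(1e6, 200, 50)$C)
  expect_error(coverage_per_locus(0, 10, 10), "positive")
  expect_error(coverage_per_locus(10, 1, 0), "positive")

  expect_equal(max_pool_size(1e6, 10, 50), 1000L)
  expect_error(max_pool_size(10, 100, 50), "unreachable")
  expect_true(max_pool_size(1e6, 20, 50) <= max_pool_size(1e6, 10, 50))
})

test_that("Poisson sampling probabilities are exact", {
  expect_equal(p_locus_sequenced(1, 3), 1 - exp(-3))
  expect_equal(p_locus_sequenced(1, 5), 1 - exp(-5))
  expect_gt(p_locus_sequenced(1, 5), 0.99)
  expect_equal(p_locus_sequenced(2, 10), 1 - 11 * exp(-10))
  expect_equal(p_locus_sequenced(1, 0), 0)
  expect_equal(p_locus_sequenced(0, 2), 1)
  expect_error(p_locus_sequenced(-1, 3), ">= 0")
})

test_that("read simulation honours coverage, allele sharing and the error model", {
  tags <- data.frame(specimen = "s", locus = "L1", allele = c("a", "b"),
                     seq = rep(random_dna(85, seed = 30), 2))
  expect_warning(r0 <- simulate_reads(tags[0, ], 5, 0, seed = 1), "empty")
  expect_equal(nrow(r0), 0)
  expect_equal(nrow(simulate_reads(tags, 0, 0, seed = 1)), 0)

  # error-free reads are exact copies of their allele
  r <- simulate_reads(tags, 50, 0, seed = 2)
  expect_true(all(r$seq == tags$seq[1]))

  # per-read error count oracle: 85 bp at 1% -> 0.85 mismatches on average
  one <- data.frame(specimen = "s", locus = "L1", allele = "a",
                    seq = random_dna(85, seed = 31))
  reads <- simulate_reads(one, 2e4, 0.01, seed = 3, allele_share = 1)
  mm <- vapply(reads$seq, hamming, numeric(1), b = one$seq)
  se <- sqrt(85 * 0.01 * 0.99 / length(mm))
  expect_lt(abs(mean(mm) - 0.85), 4 * se)

  expect_error(simulate_reads(one, 10, 0.6, seed = 1), "error_rate")
})

test_that("per-locus read counts are Poisson and match the closed form", {
  n_loci <- 1e4
  lam <- 10
  tags <- data.frame(specimen = "s", locus = sprintf("L%05d", seq_len(n_loci)),
                     allele = "a", seq = random_dna(85, seed = 32))
  reads <- simulate_reads(tags, lam, 0, seed = 4, allele_share = 1)
  counts <- table(factor(reads$locus, levels = tags$locus))
  expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / n_loci))
  expect_lt(abs(stats::var(counts) - lam), 4 * sqrt(2 * lam^2 / n_loci))

  # Monte-Carlo P(>= k reads) converges to p_locus_sequenced
  for (k in c(1, 2, 5)) {
    p_mc <- mean(counts >= k)
    p_cf <- p_locus_sequenced(k, lam)
    expect_lt(abs(p_mc - p_cf), 4 * sqrt(p_cf * (1 - p_cf) / n_loci) + 1e-6)
  }
})

test_that("sequencing errors are uniform over the three alternative bases", {
  one <- data.frame(specimen = "s", locus = "L", allele = "a",
                    seq = strrep("A", 85))
  reads <- simulate_reads(one, 3000, 0.02, seed = 5, allele_share = 1)
  subs <- unlist(strsplit(reads$seq, ""))
  subs <- subs[subs != "A"]
  expect_gt(length(subs), 1000)
  expect_gt(stats::chisq.test(table(subs))$p.value, 0.001)
})
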