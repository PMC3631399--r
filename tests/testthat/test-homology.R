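test_that("pair hits detect identity, strand, and reject chance similarity", {
  a <- random_dna(85, seed = 50)
  h <- all_vs_all_hits(c(x = a, y = a))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(h$overlap, 1)
  expect_equal(h$strand, "+")

  hrc <- all_vs_all_hits(c(x = a, y = revcomp(a)))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$identity, 1)

  # unrelated random tags should (almost) never reach E <= 1e-4
  set.seed(51)
  n_hits <- sum(vapply(1:40, function(i)
    nrow(all_vs_all_hits(c(a = random_dna(85), b = random_dna(85)))), 1L))
  expect_lte(n_hits, 1)

  expect_error(all_vs_all_hits(c(x = a)), "at least two")
})

test_that("single-linkage joins through chains and respects thresholds", {
  ids <- c("A", "B", "C")
  hits <- data.frame(query = c("A", "B"), subject = c("B", "C"),
                     identity = c(0.5, 0.5), overlap = c(0.9, 0.9),
                     evalue = 1e-9, strand = "+")
  cs <- single_linkage_cluster(ids, hits, i = 0.35, r = 0.35)
  expect_equal(length(unique(cs$membership)), 1)

  # identity 0.34 misses the 0.35 threshold; boundary is inclusive
  h2 <- data.frame(query = "A", subject = "B", identity = c(0.34),
                   overlap = 0.9, evalue = 1e-9, strand = "+")
  cs2 <- single_linkage_cluster(ids, h2, i = 0.35, r = 0.35)
  expect_equal(length(unique(cs2$membership)), 3)
  h3 <- h2; h3$identity <- 0.35
  expect_equal(length(unique(single_linkage_cluster(ids, h3)$membership)), 2)

  bad <- data.frame(query = "A", subject = "Z", identity = 1, overlap = 1,
                    evalue = 0, strand = "+")
  expect_error(single_linkage_cluster(ids, bad), "unknown")
})

test_that("union-find equals brute-force transitive closure on random graphs", {
  set.seed(52)
  for (rep_i in 1:60) {
    n <- sample(2:100, 1)
    ids <- sprintf("s%03d", seq_len(n))
    n_e <- sample(0:(2 * n), 1)
    hits <- data.frame(query = ids[sample(n, n_e, replace = TRUE)],
                       subject = ids[sample(n, n_e, replace = TRUE)],
                       identity = stats::runif(n_e), overlap = stats::runif(n_e),
                       evalue = rep(1e-9, n_e), strand = rep("+", n_e))
    i_thr <- 0.35; r_thr <- 0.35
    cs <- single_linkage_cluster(ids, hits, i_thr, r_thr)
    q <- hits[hits$identity >= i_thr & hits$overlap >= r_thr &
                hits$query != hits$subject, ]
    want <- bf_components(n, match(q$query, ids), match(q$subject, ids))
    expect_identical(canon_partition(unname(cs$membership)),
                     canon_partition(want))
    # partition invariants: disjoint cover with singletons allowed
    expect_identical(sort(names(cs$membership)), sort(ids))
    fams <- cluster_families(cs)
    expect_identical(sort(unlist(fams)), sort(ids))
  }
})

test_that("single-linkage is order-invariant; greedy clustering is not", {
  a <- random_dna(40, seed = 53)
  b <- mutate_at(a, 1:4)   # identity(a,b) = 0.9
  c3 <- mutate_at(b, 5:8)  # identity(b,c) = 0.9, identity(a,c) = 0.8
  seqs <- c(A = a, B = b, C = c3)

  g1 <- greedy_centroid_cluster(seqs, 0.85, seed_order = c("A", "B", "C"))
  g2 <- greedy_centroid_cluster(seqs, 0.85, seed_order = c("B", "A", "C"))
  expect_equal(length(unique(g1$membership)), 2) # {A,B} {C}
  expect_equal(length(unique(g2$membership)), 1) # {A,B,C}

  hits <- all_vs_all_hits(seqs, cluster_params(word_size = 8))
  cs_fwd <- single_linkage_cluster(names(seqs), hits)
  cs_rev <- single_linkage_cluster(rev(names(seqs)), hits[rev(seq_len(nrow(hits))), ])
  fam_str <- function(cs) sort(vapply(cluster_families(cs), function(f)
    paste(sort(f), collapse = ","), character(1)))
  expect_identical(fam_str(cs_fwd), fam_str(cs_rev))

  # identical sequences cluster regardless of order; threshold 1 splits others
  g3 <- greedy_centroid_cluster(c(x = a, y = a, z = b), 1.0)
  expect_equal(unname(g3$membership), c(1L, 1L, 2L))
})

test_that("paralog-containing clusters are filtered and efficiency scores purity", {
  fams_members <- list(c("sp1|L1", "sp2|L1", "sp3|L1"),
                       c("sp1|L2", "sp1|L3", "sp2|L2"))
  memb <- c(1L, 1L, 1L, 2L, 2L, 2L)
  ids <- unlist(fams_members)
  specimens <- stats::setNames(sub("\\|.*", "", ids), ids)
  cs <- structure(list(ids = ids, membership = stats::setNames(memb, ids),
                       method = "single_linkage"), class = "cluster_set")
  filt <- filter_paralogous_clusters(cs, specimens)
  expect_length(filt$kept, 1)
  expect_length(filt$removed, 1)
  expect_equal(filt$fraction_removed, 0.5)

  # perfect clustering: efficiency 1 at any stratum it covers
  truth <- stats::setNames(c("g1", "g1", "g1", "g2", "g3", "g2"), ids)
  eff <- clustering_efficiency(cs, truth, specimens, min_species = 2)
  # g1 recovered pure; g2 ({sp1|L2, sp2|L2}) shares its cluster with g3 -> impure
  expect_equal(eff, 0.5)

  truth_id <- stats::setNames(paste0("g", memb), ids)
  expect_equal(clustering_efficiency(cs, truth_id, specimens, 2), 1)
})
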