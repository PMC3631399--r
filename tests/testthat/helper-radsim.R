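# shared helpers for the radsim test suite

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# substitute the bases at 1-based positions `pos` (cyclic A->C->G->T->A)
mutate_at <- function(seq, pos) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  v[pos] <- nxt[v[pos]]
  paste(v, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# brute-force single-linkage components: boolean transitive closure
bf_components <- function(n, from, to) {
  adj <- diag(TRUE, n)
  for (e in seq_along(from)) {
    adj[from[e], to[e]] <- TRUE
    adj[to[e], from[e]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      lab <- lab + 1L
      comp[adj[i, ] > 0] <- lab
    }
  }
  comp
}

canon_partition <- function(m) match(m, unique(m))

# branch length d giving per-site substitution probability p under JC
jc_branch_for_p <- function(p) -0.75 * log(1 - 4 * p / 3)
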