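#' @useDynLib radsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")
.BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# complement lookup indexed by utf8 code
.COMP <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- utf8ToInt("T")
  m[utf8ToInt("C")] <- utf8ToInt("G")
  m[utf8ToInt("G")] <- utf8ToInt("C")
  m[utf8ToInt("T")] <- utf8ToInt("A")
  m[utf8ToInt("N")] <- utf8ToInt("N")
  m[utf8ToInt("-")] <- utf8ToInt("-")
  m
})

seq_to_int <- function(s) {
  v <- match(utf8ToInt(s), .BASE_CODES)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T}")
  v
}

int_to_seq <- function(v) intToUtf8(unname(.BASE_CODES)[v])

#' Reverse complement of a DNA string
#'
#' @param s a character vector of DNA sequences over `{A,C,G,T,N,-}`.
#' @return character vector of the same length.
#' @examples
#' revcomp("TTC")
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    codes <- .COMP[rev(utf8ToInt(x))]
    if (any(codes == 0L)) stop("sequence contains characters outside {A,C,G,T,N,-}")
    intToUtf8(codes)
  }, character(1), USE.NAMES = FALSE)
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
# The seed argument is forced *before* the caller's RNG state is saved, so a
# seed expression that itself draws from the RNG (e.g. sample.int()) still
# advances the caller's stream.
with_seed <- function(seed, code) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a named RNG substream seed
#'
#' Every stage of the simulator draws its randomness from a seed derived
#' deterministically from one master seed and a stage label, so stages can be
#' re-run in isolation and stay reproducible when upstream stages change.
#'
#' @param seed master seed (integer).
#' @param label character stage label, e.g. `"genomes"`, `"reads:sp01"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1013904223
  as.integer(((seed %% 97561) * 2654435761 + h * 97 + seed %% 7919) %% 2147483647)
}

# Mutate integer-coded sequence: each site independently substituted with
# probability p, uniformly to one of the 3 other bases (no back-mutation
# bookkeeping; this is the per-branch Bernoulli form of Jukes-Cantor).
mutate_sites <- function(v, p) {
  if (p < 0 || p > 1) stop("substitution probability must be in [0,1]")
  if (p == 0) return(v)
  idx <- which(stats::runif(length(v)) < p)
  if (length(idx))
    v[idx] <- ((v[idx] - 1L + sample(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  v
}

# Per-site substitution probability for a Jukes-Cantor branch of length d
# (expected substitutions per site).
jc_sub_prob <- function(d) {
  if (any(d < 0)) stop("branch length must be non-negative")
  0.75 * (1 - exp(-4 * d / 3))
}

#' Expected p-distance under Jukes-Cantor
#'
#' Closed-form expected proportion of differing sites after evolving a
#' sequence for `d` expected substitutions per site.
#'
#' @param d branch length (substitutions/site), non-negative.
#' @return expected p-distance, `(3/4) (1 - exp(-4 d / 3))`.
#' @export
jc_expected_pdist <- function(d) jc_sub_prob(d)

# Union-find with path halving; edges as parallel integer vectors.
# Returns component labels 1..k in order of first appearance.
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Shannon entropy (bits/base) of a DNA word; used to mask low-complexity seeds.
word_entropy <- function(word) {
  tab <- tabulate(match(strsplit(word, "", fixed = TRUE)[[1]], DNA_BASES), 4L)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
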