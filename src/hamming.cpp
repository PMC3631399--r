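#include <Rcpp.h>
using namespace Rcpp;

static inline int ham(const char* a, const char* b, R_xlen_t n) {
  int d = 0;
  for (R_xlen_t k = 0; k < n; ++k) if (a[k] != b[k]) ++d;
  return d;
}

// Pairwise Hamming distances among equal-length strings.
// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  IntegerMatrix out(n, n);
  if (n == 0) return out;
  R_xlen_t len = LENGTH(STRING_ELT(x, 0));
  std::vector<const char*> p(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(x, i)) != len) stop("all sequences must have equal length");
    p[i] = CHAR(STRING_ELT(x, i));
  }
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      int d = ham(p[i], p[j], len);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}

// Hamming distances between every x[i] and every y[j] (rows = x).
// [[Rcpp::export]]
IntegerMatrix hamming_cross_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = x.size(), m = y.size();
  IntegerMatrix out(n, m);
  if (n == 0 || m == 0) return out;
  R_xlen_t len = LENGTH(STRING_ELT(x, 0));
  for (R_xlen_t i = 0; i < n; ++i)
    if (LENGTH(STRING_ELT(x, i)) != len) stop("all sequences must have equal length");
  for (R_xlen_t j = 0; j < m; ++j)
    if (LENGTH(STRING_ELT(y, j)) != len) stop("all sequences must have equal length");
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* a = CHAR(STRING_ELT(x, i));
    for (R_xlen_t j = 0; j < m; ++j)
      out(i, j) = ham(a, CHAR(STRING_ELT(y, j)), len);
  }
  return out;
}

// Hamming distance between one pair of equal-length strings (used on
// whole-genome sequences where an R-level split would be wasteful).
// [[Rcpp::export]]
double hamming_pair_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  double d = 0;
  for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
  return d;
}
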