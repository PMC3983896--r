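#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Generalised Levenshtein distance: minimal total cost of single-character
// insertions, deletions and substitutions turning `a` into `b`.
// Unit costs give the classical edit distance.
static double led_one(const char *a, R_xlen_t n, const char *b, R_xlen_t m,
                      double ci, double cd, double cs) {
  std::vector<double> prev(m + 1), cur(m + 1);
  for (R_xlen_t j = 0; j <= m; ++j) prev[j] = j * ci;
  for (R_xlen_t i = 1; i <= n; ++i) {
    cur[0] = i * cd;
    for (R_xlen_t j = 1; j <= m; ++j) {
      double sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : cs);
      double del = prev[j] + cd;
      double ins = cur[j - 1] + ci;
      double best = sub < del ? sub : del;
      cur[j] = best < ins ? best : ins;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
NumericVector led_pairs_cpp(CharacterVector a, CharacterVector b,
                            double ci, double cd, double cs) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    out[i] = led_one(sa, LENGTH(STRING_ELT(a, i)), sb, LENGTH(STRING_ELT(b, i)),
                     ci, cd, cs);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix led_matrix_cpp(CharacterVector x, CharacterVector y,
                             double ci, double cd, double cs) {
  R_xlen_t n = x.size(), m = y.size();
  NumericMatrix out(n, m);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *sx = CHAR(STRING_ELT(x, i));
    R_xlen_t lx = LENGTH(STRING_ELT(x, i));
    for (R_xlen_t j = 0; j < m; ++j) {
      const char *sy = CHAR(STRING_ELT(y, j));
      out(i, j) = led_one(sx, lx, sy, LENGTH(STRING_ELT(y, j)), ci, cd, cs);
    }
  }
  return out;
}
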