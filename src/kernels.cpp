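#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy match counts (Richman & Moorman): over the N - m template
// positions, count pairs (i < j) whose length-m windows match under the
// Chebyshev metric within r (B), and whose length-(m+1) windows also match (A).
// Self-matches are excluded by construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m; // template count; extension x[i+m] exists for i < nt
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Diagonal-line statistics of the recurrence matrix R[t,t'] = 1(s_t == s_t'),
// off the main diagonal only. Returns (sum over lines with length >= lmin of
// l, i.e. the weighted numerator) and the number of off-diagonal recurrence
// points. Lines on symmetric offsets are counted on both sides.
// [[Rcpp::export(name = ".rqa_det_counts")]]
NumericVector rqa_det_counts(IntegerVector s, int lmin) {
  int n = s.size();
  double num = 0.0, pts = 0.0;
  for (int d = 1; d < n; ++d) {
    int run = 0;
    for (int t = 0; t + d < n; ++t) {
      if (s[t] == s[t + d]) {
        ++run;
        pts += 1.0;
      } else {
        if (run >= lmin) num += run;
        run = 0;
      }
    }
    if (run >= lmin) num += run;
  }
  // symmetric lower triangle mirrors the upper one exactly
  return NumericVector::create(2.0 * num, 2.0 * pts);
}

// LZ76 complexity counter c(S): exhaustive-history parsing
// (Kaspar & Schuster 1987 algorithm).
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
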