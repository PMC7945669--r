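#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Pairwise alignment by dynamic programming with linear gap penalty.
// free_ends = false: global Needleman-Wunsch (every gap charged).
// free_ends = true:  overlap alignment (leading/trailing gaps in either
// sequence are free) — the appropriate formulation when the inputs are
// fragments of the same gene sequenced over different spans, where charging
// terminal gaps makes scattered, co-optimal tail placements possible.
// Fill ties are resolved diagonal > up > left ("up" consumes a character
// of `a`, writing a gap into `b`).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap,
                  bool free_ends = true) {
  const int n = (int) a.size(), m = (int) b.size();
  const int W = m + 1;
  std::vector<double> S((size_t)(n + 1) * W);
  std::vector<unsigned char> P((size_t)(n + 1) * W);
  S[0] = 0.0; P[0] = 0;
  for (int i = 1; i <= n; ++i) {
    S[(size_t)i * W] = free_ends ? 0.0 : i * gap;
    P[(size_t)i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S[j] = free_ends ? 0.0 : j * gap;
    P[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = S[(size_t)(i - 1) * W + (j - 1)] + (ai == b[j - 1] ? match : mismatch);
      double u = S[(size_t)(i - 1) * W + j] + gap;
      double l = S[(size_t)i * W + (j - 1)] + gap;
      size_t k = (size_t)i * W + j;
      if (d >= u && d >= l)      { S[k] = d; P[k] = 0; }
      else if (u >= l)           { S[k] = u; P[k] = 1; }
      else                       { S[k] = l; P[k] = 2; }
    }
  }
  int bi = n, bj = m;
  double best = S[(size_t)n * W + m];
  if (free_ends) {
    // best end on the last row or column; prefer the corner, then the last
    // column bottom-up, then the last row right-to-left (deterministic)
    for (int i = n; i >= 0; --i) {
      double v = S[(size_t)i * W + m];
      if (v > best) { best = v; bi = i; bj = m; }
    }
    for (int j = m; j >= 0; --j) {
      double v = S[(size_t)n * W + j];
      if (v > best) { best = v; bi = n; bj = j; }
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  // trailing free gaps beyond the chosen end cell
  for (int i = n; i > bi; --i) { ra += a[i - 1]; rb += '-'; }
  for (int j = m; j > bj; --j) { ra += '-'; rb += b[j - 1]; }
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    if (free_ends && (i == 0 || j == 0)) break;
    unsigned char p = P[(size_t)i * W + j];
    if (p == 0 && i > 0 && j > 0) { ra += a[i - 1]; rb += b[j - 1]; --i; --j; }
    else if (p == 1 && i > 0)     { ra += a[i - 1]; rb += '-';      --i; }
    else                          { ra += '-';      rb += b[j - 1]; --j; }
  }
  // leading free gaps before the start cell
  while (i > 0) { ra += a[i - 1]; rb += '-'; --i; }
  while (j > 0) { ra += '-'; rb += b[j - 1]; --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best, _["a"] = ra, _["b"] = rb);
}
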