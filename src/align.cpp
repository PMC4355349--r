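#include <Rcpp.h>
#include <climits>
#include <cstdlib>
#include <algorithm>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with linear gap penalty.
// band < 0 disables banding; otherwise cells with |i - j| > band + |n - m|
// are unreachable (the diagonal allowance always accommodates the length
// difference, so the global end cell stays reachable).
// Tie-break in traceback: diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int band,
                      int match, int mismatch, int gap,
                      bool keep_alignment) {
  const int n = (int) a.size(), m = (int) b.size();
  const int NEG = INT_MIN / 4;
  const int allow = (band < 0) ? std::max(n, m) + 1
                               : band + std::abs(n - m);
  std::vector<int> S((size_t)(n + 1) * (m + 1), NEG);
  std::vector<unsigned char> T((size_t)(n + 1) * (m + 1), 0);
  const size_t W = (size_t) m + 1;
  S[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (j > allow) break;
    S[j] = gap * j; T[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    if (i <= allow) { S[(size_t)i * W] = gap * i; T[(size_t)i * W] = 3; }
    const int jlo = std::max(1, i - allow), jhi = std::min(m, i + allow);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG; unsigned char tb = 0;
      const int d = S[(size_t)(i - 1) * W + (j - 1)];
      if (d > NEG) {
        const int sc = d + ((a[i - 1] == b[j - 1]) ? match : mismatch);
        if (sc > best) { best = sc; tb = 1; }
      }
      const int u = S[(size_t)(i - 1) * W + j];
      if (u > NEG) { const int sc = u + gap; if (sc > best) { best = sc; tb = 3; } }
      const int l = S[(size_t)i * W + (j - 1)];
      if (l > NEG) { const int sc = l + gap; if (sc > best) { best = sc; tb = 2; } }
      S[(size_t)i * W + j] = best; T[(size_t)i * W + j] = tb;
    }
  }
  int i = n, j = m, matches = 0, cols = 0;
  std::string ra, rb;
  while (i > 0 || j > 0) {
    const unsigned char t = T[(size_t)i * W + j];
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ++matches;
      if (keep_alignment) { ra += a[i - 1]; rb += b[j - 1]; }
      --i; --j;
    } else if (t == 3) {
      if (keep_alignment) { ra += a[i - 1]; rb += '-'; }
      --i;
    } else if (t == 2) {
      if (keep_alignment) { ra += '-'; rb += b[j - 1]; }
      --j;
    } else {
      stop("alignment traceback escaped the band"); // unreachable by construction
    }
    ++cols;
  }
  List out = List::create(_["score"] = S[(size_t)n * W + m],
                          _["matches"] = matches,
                          _["columns"] = cols);
  if (keep_alignment) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    out["aligned_a"] = ra;
    out["aligned_b"] = rb;
  }
  return out;
}

// Spaced-seed keys: for each window offset o (0-based) of s, the string of
// characters at the seed's care positions. care is 0-based within the window.
// [[Rcpp::export]]
CharacterVector cpp_spaced_keys(std::string s, IntegerVector care, int pattern_length) {
  const int n = (int) s.size(), k = care.size();
  const int nw = std::max(0, n - pattern_length + 1);
  CharacterVector out(nw);
  std::string key((size_t) k, ' ');
  for (int o = 0; o < nw; ++o) {
    for (int t = 0; t < k; ++t) key[(size_t) t] = s[(size_t)(o + care[t])];
    out[o] = key;
  }
  return out;
}
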