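#include <Rcpp.h>

// Exhaustive LZ76 phrase count (Kaspar-Schuster scheme). The sequence is
// scanned left to right; each phrase is the shortest new word, i.e. the
// longest prefix of the remainder that already occurs starting before the
// current position (overlap into the phrase allowed), plus one novel symbol.
// The final phrase may be a pure copy when the match runs to the end.
// [[Rcpp::export]]
int lz76_count(Rcpp::IntegerVector s) {
  const int n = s.size();
  int c = 0;
  int l = 0;
  while (l < n) {
    int kmax = 0;  // longest prefix of s[l..] seen starting at some p < l
    for (int p = 0; p < l; ++p) {
      int k = 0;
      while (l + k < n && s[p + k] == s[l + k]) ++k;
      if (k > kmax) kmax = k;
      if (l + kmax >= n) break;
    }
    ++c;
    l += kmax + 1;
  }
  return c;
}
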