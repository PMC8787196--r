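#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Levenshtein distance with unit costs, two-row dynamic program.
// [[Rcpp::export]]
int levenshtein_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), curr(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    curr[0] = i;
    const String ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int cost = (ai == b[j - 1]) ? 0 : 1;
      int best = prev[j - 1] + cost;          // substitution / match
      if (prev[j] + 1 < best) best = prev[j] + 1;   // deletion
      if (curr[j - 1] + 1 < best) best = curr[j - 1] + 1; // insertion
      curr[j] = best;
    }
    std::swap(prev, curr);
  }
  return prev[m];
}
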