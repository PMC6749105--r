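#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Semi-global 3' adapter search, cutadapt-style error model.
//
// For each read we find the best occurrence of the adapter (or, at the read's
// 3' end, of an adapter prefix) and return the number of bases to keep
// (i.e. the 0-based start of the chosen alignment).  An occurrence qualifies
// when its edit distance is <= floor(max_error_rate * aligned_adapter_length)
// and the aligned adapter length is >= min_overlap.  Among qualifying
// occurrences the one with minimal error rate wins; ties are broken by the
// leftmost start (longest trim).
//
// DP over (adapter position j, read position i) with free start anywhere in
// the read; each cell tracks (min edit cost, min start achieving it).
// Candidate cells are j == m (full adapter, internal match: everything from
// the start onward is removed) and i == n (adapter prefix running off the
// read end).

// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               double max_error_rate, int min_overlap) {
  const int m = adapter.size();
  if (m == 0) stop("adapter must be non-empty");
  if (max_error_rate < 0 || max_error_rate >= 1)
    stop("max_error_rate must be in [0, 1)");
  if (min_overlap < 1) stop("min_overlap must be >= 1");

  const R_xlen_t nr = reads.size();
  IntegerVector keep(nr);

  // floor(rate * l) budget per aligned adapter length l
  std::vector<int> budget(m + 1);
  for (int l = 0; l <= m; ++l)
    budget[l] = (int)std::floor(max_error_rate * l + 1e-9);

  std::vector<int> cost_prev(m + 1), cost_cur(m + 1);
  std::vector<int> start_prev(m + 1), start_cur(m + 1);

  for (R_xlen_t r = 0; r < nr; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    const int n = LENGTH(STRING_ELT(reads, r));
    keep[r] = n;
    if (n == 0) continue;

    double best_rate = 2.0; // > any achievable rate
    int best_start = n;

    // column i = 0 (no read consumed yet): adapter chars are deletions
    for (int j = 0; j <= m; ++j) { cost_prev[j] = j; start_prev[j] = 0; }
    // i == 0 column cannot produce a qualifying suffix candidate unless n==0

    for (int i = 1; i <= n; ++i) {
      cost_cur[0] = 0;
      start_cur[0] = i; // alignment may start at i (0 adapter consumed)
      const char rc = rd[i - 1];
      for (int j = 1; j <= m; ++j) {
        const int sub = (adapter[j - 1] == rc &&
                         (rc == 'A' || rc == 'C' || rc == 'G' || rc == 'T')) ? 0 : 1;
        int c = cost_prev[j - 1] + sub;           // (mis)match
        int s = start_prev[j - 1];
        int c2 = cost_prev[j] + 1;                // gap in adapter row (adapter char unmatched)
        if (c2 < c || (c2 == c && start_prev[j] < s)) { c = c2; s = start_prev[j]; }
        int c3 = cost_cur[j - 1] + 1;             // gap in read (read char unmatched)
        if (c3 < c || (c3 == c && start_cur[j - 1] < s)) { c = c3; s = start_cur[j - 1]; }
        cost_cur[j] = c;
        start_cur[j] = s;
      }
      // candidate: full adapter matched, ends at read position i
      {
        const int c = cost_cur[m], s = start_cur[m];
        if (m >= min_overlap && c <= budget[m] && s < n) {
          const double rate = (double)c / m;
          if (rate < best_rate - 1e-12 ||
              (std::abs(rate - best_rate) <= 1e-12 && s < best_start)) {
            best_rate = rate; best_start = s;
          }
        }
      }
      if (i == n) {
        // candidates: adapter prefix j aligned flush with the read end
        for (int j = min_overlap; j < m; ++j) {
          const int c = cost_cur[j], s = start_cur[j];
          if (c <= budget[j] && s < n) {
            const double rate = (double)c / j;
            if (rate < best_rate - 1e-12 ||
                (std::abs(rate - best_rate) <= 1e-12 && s < best_start)) {
              best_rate = rate; best_start = s;
            }
          }
        }
      }
      std::swap(cost_prev, cost_cur);
      std::swap(start_prev, start_cur);
    }

    if (best_rate <= 1.0) keep[r] = best_start;
  }
  return keep;
}
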