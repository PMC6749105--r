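#include <Rcpp.h>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

// FNV-1a 64-bit string hash, hex-encoded; used for nonredundant sequence-set
// entry identifiers and config fingerprints in run provenance logs.

// [[Rcpp::export]]
CharacterVector fnv1a64_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    const int n = LENGTH(STRING_ELT(x, i));
    uint64_t h = 14695981039346656037ULL;
    for (int j = 0; j < n; ++j) {
      h ^= (uint64_t)(unsigned char)s[j];
      h *= 1099511628211ULL;
    }
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
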