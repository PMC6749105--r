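#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Ungapped end-to-end placement of short reads against a set of reference
// sequences, reporting every placement that achieves the per-read minimal
// mismatch count (when <= max_mm).  Equivalent to the brute-force scan over
// all (reference, offset[, strand]) pairs: candidate placements are generated
// with max_mm + 1 disjoint exact seeds (pigeonhole: any placement with
// <= max_mm mismatches leaves at least one seed mismatch-free), then verified
// by full comparison.  Reads too short for informative seeds fall back to the
// exhaustive scan.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

struct Hit { int ref; int pos; int strand; int mm; };

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > SeedIndex;

// count mismatches of read vs refs[ref] at offset pos, early exit beyond cap
static inline int count_mm(const std::string &read, const std::string &ref,
                           int pos, int cap) {
  int mm = 0;
  const int L = read.size();
  for (int i = 0; i < L; ++i) {
    const char a = read[i], b = ref[pos + i];
    if (a != b || base_code(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static void build_index(const std::vector<std::string> &refs, int s, SeedIndex &idx) {
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string &seq = refs[r];
    const int n = seq.size();
    if (n < s) continue;
    uint64_t key = 0, mask = (s >= 32) ? ~0ULL : ((1ULL << (2 * s)) - 1);
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(seq[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= s)
        idx[key].push_back(std::make_pair((int)r, i - s + 1));
    }
  }
}

static void scan_exhaustive(const std::string &read,
                            const std::vector<std::string> &refs,
                            int strand, int max_mm, std::vector<Hit> &hits) {
  const int L = read.size();
  for (size_t r = 0; r < refs.size(); ++r) {
    const int n = refs[r].size();
    for (int p = 0; p + L <= n; ++p) {
      const int mm = count_mm(read, refs[r], p, max_mm);
      if (mm <= max_mm) {
        Hit h; h.ref = (int)r; h.pos = p; h.strand = strand; h.mm = mm;
        hits.push_back(h);
      }
    }
  }
}

static void scan_seeded(const std::string &read,
                        const std::vector<std::string> &refs,
                        std::map<int, SeedIndex> &indexes,
                        int strand, int max_mm, int s, std::vector<Hit> &hits) {
  const int L = read.size();
  const int t = max_mm + 1;
  if (indexes.find(s) == indexes.end())
    build_index(refs, s, indexes[s]);
  const SeedIndex &idx = indexes[s];
  std::vector<std::pair<int,int> > seen; // (ref, pos) already verified
  for (int q = 0; q < t; ++q) {
    const int off = q * s;
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < s; ++i) {
      const int c = base_code(read[off + i]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    SeedIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<std::pair<int,int> > &cand = it->second;
    for (size_t j = 0; j < cand.size(); ++j) {
      const int r = cand[j].first;
      const int p = cand[j].second - off;
      if (p < 0 || p + L > (int)refs[r].size()) continue;
      std::pair<int,int> rp(r, p);
      if (std::find(seen.begin(), seen.end(), rp) != seen.end()) continue;
      seen.push_back(rp);
      const int mm = count_mm(read, refs[r], p, max_mm);
      if (mm <= max_mm) {
        Hit h; h.ref = r; h.pos = p; h.strand = strand; h.mm = mm;
        hits.push_back(h);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector refs,
                          int max_mm, bool rev_comp) {
  const R_xlen_t nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nf);
  for (R_xlen_t i = 0; i < nf; ++i) R[i] = std::string(CHAR(STRING_ELT(refs, i)));

  std::map<int, SeedIndex> indexes;
  std::vector<int> o_read, o_ref, o_start, o_end, o_mm, o_strand;

  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::string rd(CHAR(STRING_ELT(reads, i)));
    const int L = rd.size();
    if (L == 0) continue;
    hits.clear();

    const int t = max_mm + 1;
    int s = L / t; if (s > 16) s = 16;
    const bool seeded = (s >= 4);

    if (seeded) scan_seeded(rd, R, indexes, 1, max_mm, s, hits);
    else scan_exhaustive(rd, R, 1, max_mm, hits);

    if (rev_comp) {
      std::string rc(L, 'N');
      for (int j = 0; j < L; ++j) rc[j] = comp_base(rd[L - 1 - j]);
      if (seeded) scan_seeded(rc, R, indexes, -1, max_mm, s, hits);
      else scan_exhaustive(rc, R, -1, max_mm, hits);
    }
    if (hits.empty()) continue;

    int best = max_mm;
    for (size_t h = 0; h < hits.size(); ++h) best = std::min(best, hits[h].mm);
    for (size_t h = 0; h < hits.size(); ++h) {
      if (hits[h].mm != best) continue;
      o_read.push_back((int)i + 1);
      o_ref.push_back(hits[h].ref + 1);
      o_start.push_back(hits[h].pos);
      o_end.push_back(hits[h].pos + L);
      o_strand.push_back(hits[h].strand);
      o_mm.push_back(hits[h].mm);
    }
  }

  return DataFrame::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["ref_start"] = wrap(o_start), _["ref_end"] = wrap(o_end),
    _["strand"] = wrap(o_strand), _["mismatches"] = wrap(o_mm),
    _["stringsAsFactors"] = false);
}
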