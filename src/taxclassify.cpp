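#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// k-mer -> LCA taxonomic classification engine (Kraken-style, minimal).
// k <= 31 so a k-mer packs into 62 bits; k-mers are stored in canonical form
// (lexicographic minimum of forward and reverse-complement encoding).

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static uint64_t canonical(uint64_t fwd, int k) {
  uint64_t rc = 0, x = fwd;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return fwd < rc ? fwd : rc;
}

static std::string decode_kmer(uint64_t key, int k) {
  static const char *b = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[key & 3ULL]; key >>= 2; }
  return s;
}

// depths from 1-based parent vector (root has parent[i] == i)
static std::vector<int> node_depths(const IntegerVector &parent) {
  const int n = parent.size();
  std::vector<int> depth(n, -1);
  for (int i = 0; i < n; ++i) {
    int d = 0, j = i;
    while (parent[j] != j + 1) { j = parent[j] - 1; ++d; if (d > n) stop("taxonomy has a cycle"); }
    depth[i] = d;
  }
  return depth;
}

static int lca(int a, int b, const IntegerVector &parent, const std::vector<int> &depth) {
  // 1-based taxon ids
  while (depth[a - 1] > depth[b - 1]) a = parent[a - 1];
  while (depth[b - 1] > depth[a - 1]) b = parent[b - 1];
  while (a != b) { a = parent[a - 1]; b = parent[b - 1]; }
  return a;
}

// [[Rcpp::export]]
List build_kmer_lca_cpp(CharacterVector genomes, IntegerVector genome_taxon,
                        IntegerVector parent, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<int> depth = node_depths(parent);
  std::unordered_map<uint64_t, int> db;
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);

  for (R_xlen_t g = 0; g < genomes.size(); ++g) {
    const char *seq = CHAR(STRING_ELT(genomes, g));
    const int n = LENGTH(STRING_ELT(genomes, g));
    const int taxon = genome_taxon[g];
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(seq[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        const uint64_t can = canonical(key, k);
        std::unordered_map<uint64_t, int>::iterator it = db.find(can);
        if (it == db.end()) db[can] = taxon;
        else if (it->second != taxon) it->second = lca(it->second, taxon, parent, depth);
      }
    }
  }

  // deterministic output order
  std::vector<std::pair<uint64_t,int> > out(db.begin(), db.end());
  std::sort(out.begin(), out.end());
  const R_xlen_t m = out.size();
  CharacterVector kmers(m);
  IntegerVector taxa(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmers[i] = decode_kmer(out[i].first, k);
    taxa[i] = out[i].second;
  }
  return List::create(_["kmer"] = kmers, _["taxon"] = taxa);
}

// [[Rcpp::export]]
IntegerVector classify_reads_cpp(CharacterVector reads, CharacterVector db_kmers,
                                 IntegerVector db_taxa, IntegerVector parent,
                                 int k, int min_len) {
  std::vector<int> depth = node_depths(parent);
  const int ntax = parent.size();

  std::unordered_map<uint64_t, int> db;
  db.reserve(db_kmers.size() * 2 + 1);
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t i = 0; i < db_kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(db_kmers, i));
    uint64_t key = 0;
    for (int j = 0; j < k; ++j) {
      const int c = base_code(s[j]);
      if (c < 0) stop("invalid base in database k-mer");
      key = (key << 2) | (uint64_t)c;
    }
    db[key & mask] = db_taxa[i];
  }

  // leaves = taxa that are nobody's parent
  std::vector<bool> is_leaf(ntax, true);
  for (int i = 0; i < ntax; ++i)
    if (parent[i] != i + 1) is_leaf[parent[i] - 1] = false;
  std::vector<int> leaves;
  for (int i = 0; i < ntax; ++i) if (is_leaf[i]) leaves.push_back(i + 1);

  IntegerVector out(reads.size(), NA_INTEGER);
  std::vector<int> votes(ntax + 1, 0);
  std::vector<int> touched;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *seq = CHAR(STRING_ELT(reads, r));
    const int n = LENGTH(STRING_ELT(reads, r));
    if (n < min_len || n < k) continue;

    touched.clear();
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(seq[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        std::unordered_map<uint64_t, int>::const_iterator it = db.find(canonical(key, k));
        if (it != db.end()) {
          if (votes[it->second] == 0) touched.push_back(it->second);
          ++votes[it->second];
        }
      }
    }
    if (touched.empty()) continue;

    // root-to-leaf path scoring; ties resolved to the LCA of tied leaves
    int best_w = 0, assigned = NA_INTEGER;
    for (size_t l = 0; l < leaves.size(); ++l) {
      int w = 0, node = leaves[l];
      for (;;) {
        w += votes[node];
        if (parent[node - 1] == node) break;
        node = parent[node - 1];
      }
      if (w == 0) continue;
      if (w > best_w) { best_w = w; assigned = leaves[l]; }
      else if (w == best_w && assigned != NA_INTEGER)
        assigned = lca(assigned, leaves[l], parent, depth);
    }
    out[r] = assigned;

    for (size_t i = 0; i < touched.size(); ++i) votes[touched[i]] = 0;
  }
  return out;
}
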