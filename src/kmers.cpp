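#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 2-bit base encoding: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline std::string decode_kmer(uint64_t enc, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[enc & 3ULL];
    enc >>= 2;
  }
  return s;
}

// Encode a k-mer string; returns false if it contains a non-ACGT base.
static inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t e = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    e = (e << 2) | (uint64_t)c;
  }
  out = e;
  return true;
}

static inline uint64_t revcomp_enc(uint64_t e, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (e & 3ULL));
    e >>= 2;
  }
  return r;
}

// Count canonical k-mers (lexicographic min of k-mer and reverse complement)
// over a set of sequences. Windows containing non-ACGT characters are skipped.
// [[Rcpp::export(name = ".kmer_count_cpp")]]
DataFrame kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 22);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int n = (int)LENGTH(STRING_ELT(seqs, si));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((3ULL - (uint64_t)c) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = std::min(fwd, rev);
        ++counts[canon];
      }
    }
  }
  R_xlen_t m = (R_xlen_t)counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  // sort keys for deterministic output order
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    count[i] = counts[keys[i]];
  }
  return DataFrame::create(Named("kmer") = kmer, Named("count") = count,
                           Named("stringsAsFactors") = false);
}

// bucket entry: for k <= 29 the masked value (2k bits) and the masked
// position (5 bits) are packed into one 64-bit key; larger k uses a wider
// struct-based fallback.
struct MaskEntry {
  uint64_t val;   // masked encoding (2 bits zeroed at masked position)
  uint32_t pos;   // canonical masked position
  uint32_t idx;   // k-mer index
};

// Heterozygous k-mer pair discovery: bucket every k-mer by its sequence with
// one position wildcarded (both orientations, canonicalized), and emit a pair
// for every bucket holding exactly two distinct k-mers. Pairs are deduplicated
// across positions. Orientation-aware: a pair is found even if the two input
// k-mers canonicalize to opposite strands.
// [[Rcpp::export(name = ".het_pairs_cpp")]]
DataFrame het_pairs_cpp(CharacterVector kmers, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  R_xlen_t n = kmers.size();
  std::vector<uint64_t> enc(n), renc(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("all k-mers must have length k");
    uint64_t e;
    if (!encode_kmer(s, k, e)) stop("k-mers must contain only A/C/G/T");
    enc[i] = e;
    renc[i] = revcomp_enc(e, k);
  }
  std::vector<std::pair<uint32_t, uint32_t>> pairs;
  if (2 * k + 5 <= 64) {
    // fast path: (masked value, position) packed into one 64-bit key
    std::vector<std::pair<uint64_t, uint32_t>> entries;
    entries.reserve((size_t)n * k);
    for (R_xlen_t i = 0; i < n; ++i) {
      for (int p = 0; p < k; ++p) {
        uint64_t mf = enc[i] & ~(3ULL << (2 * (k - 1 - p)));
        int pr = k - 1 - p;
        uint64_t mr = renc[i] & ~(3ULL << (2 * (k - 1 - pr)));
        uint64_t key;
        uint64_t kf = (mf << 5) | (uint64_t)p;
        uint64_t kr = (mr << 5) | (uint64_t)pr;
        key = (kf <= kr) ? kf : kr;
        entries.push_back({key, (uint32_t)i});
      }
    }
    std::sort(entries.begin(), entries.end());
    size_t i = 0, ne = entries.size();
    while (i < ne) {
      size_t j = i + 1;
      while (j < ne && entries[j].first == entries[i].first) ++j;
      if (j - i == 2 && entries[i].second != entries[i + 1].second) {
        uint32_t a = entries[i].second, b = entries[i + 1].second;
        if (a > b) std::swap(a, b);
        pairs.push_back({a, b});
      }
      i = j;
    }
  } else {
    std::vector<MaskEntry> entries;
    entries.reserve((size_t)n * k);
    for (R_xlen_t i = 0; i < n; ++i) {
      for (int p = 0; p < k; ++p) {
        uint64_t mf = enc[i] & ~(3ULL << (2 * (k - 1 - p)));
        int pr = k - 1 - p;
        uint64_t mr = renc[i] & ~(3ULL << (2 * (k - 1 - pr)));
        // canonical (value, position) over the two orientations
        uint64_t v; uint32_t pp;
        if (mf < mr || (mf == mr && p <= pr)) { v = mf; pp = (uint32_t)p; }
        else { v = mr; pp = (uint32_t)pr; }
        entries.push_back({v, pp, (uint32_t)i});
      }
    }
    std::sort(entries.begin(), entries.end(),
              [](const MaskEntry& a, const MaskEntry& b) {
      if (a.val != b.val) return a.val < b.val;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.idx < b.idx;
    });
    size_t i = 0, ne = entries.size();
    while (i < ne) {
      size_t j = i + 1;
      while (j < ne && entries[j].val == entries[i].val &&
             entries[j].pos == entries[i].pos) ++j;
      if (j - i == 2 && entries[i].idx != entries[i + 1].idx) {
        uint32_t a = entries[i].idx, b = entries[i + 1].idx;
        if (a > b) std::swap(a, b);
        pairs.push_back({a, b});
      }
      i = j;
    }
  }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  R_xlen_t np = (R_xlen_t)pairs.size();
  IntegerVector ia(np), ib(np);
  for (R_xlen_t q = 0; q < np; ++q) {
    ia[q] = (int)pairs[q].first + 1;   // 1-based for R
    ib[q] = (int)pairs[q].second + 1;
  }
  return DataFrame::create(Named("i") = ia, Named("j") = ib,
                           Named("stringsAsFactors") = false);
}
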