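#ifndef KMERDEPTH_KMER_H
#define KMERDEPTH_KMER_H

#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>

namespace kmerdepth {

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// A=0, C=1, G=2, T=3; case-folded; anything else (N, IUPAC, gaps) -> -1
inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char complementChar(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// reverse complement of a 2-bit packed k-mer; complement is ~b because
// A(0)<->T(3), C(1)<->G(2)
inline uint64_t revComp(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2)  & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4)  & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8)  & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

// lexicographically smaller of the word and its reverse complement; with the
// leftmost base in the most significant bits this equals numeric min
inline uint64_t canonical(uint64_t x, int k) {
  uint64_t r = revComp(x, k);
  return x < r ? x : r;
}

inline std::string decodeKmer(uint64_t x, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = BASES[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// false on non-ACGT input
inline bool encodeKmer(const char* s, int k, uint64_t& out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (uint64_t)b;
  }
  out = x;
  return true;
}

// Slide a k-window over s, emitting canonical codes for ACGT-only windows.
// Counts every character in nNucl; non-ACGT characters break the window.
template <typename F>
inline void scanString(const char* s, size_t n, int k,
                       double& nNucl, double& nKmer, F&& emit) {
  nNucl += (double)n;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t x = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) { run = 0; x = 0; continue; }
    x = ((x << 2) | (uint64_t)b) & mask;
    if (run < k) ++run;
    if (run >= k) {
      nKmer += 1.0;
      emit(i + 1 - (size_t)k, canonical(x, k));
    }
  }
}

struct IndexEntry {
  uint32_t count;
  int32_t rec;   // record index of first occurrence
  uint32_t pos;  // 0-based leftmost coordinate of first occurrence
};

// flat open-addressing hash map (linear probing, power-of-2 capacity) for
// uint64 k-mer codes; canonical codes can never be all-ones, so ~0 serves as
// the empty sentinel. Node-based maps are several times slower here because
// every genome-scale operation is one random memory access per probe.
template <typename V>
struct OAMap {
  static constexpr uint64_t EMPTY = ~0ULL;
  std::vector<uint64_t> keys;
  std::vector<V> vals;
  uint64_t mask = 0;
  size_t n = 0;

  static inline uint64_t mixHash(uint64_t x) {  // splitmix64 finalizer
    x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27; x *= 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }

  void init(double expected) {
    size_t cap = 1024;
    while ((double)cap * 0.7 < expected) cap <<= 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, V());
    mask = (uint64_t)cap - 1;
    n = 0;
  }

  size_t capacity() const { return keys.size(); }

  const V* find(uint64_t key) const {
    uint64_t i = mixHash(key) & mask;
    for (;;) {
      if (keys[i] == key) return &vals[i];
      if (keys[i] == EMPTY) return nullptr;
      i = (i + 1) & mask;
    }
  }

  // returns (slot value pointer, inserted?); grows at 70% load
  std::pair<V*, bool> emplace(uint64_t key) {
    if ((double)n >= (double)keys.size() * 0.7) grow();
    uint64_t i = mixHash(key) & mask;
    for (;;) {
      if (keys[i] == key) return {&vals[i], false};
      if (keys[i] == EMPTY) {
        keys[i] = key;
        ++n;
        return {&vals[i], true};
      }
      i = (i + 1) & mask;
    }
  }

  void grow() {
    std::vector<uint64_t> ok;
    std::vector<V> ov;
    ok.swap(keys);
    ov.swap(vals);
    keys.assign(ok.size() * 2, EMPTY);
    vals.assign(ok.size() * 2, V());
    mask = (uint64_t)keys.size() - 1;
    for (size_t j = 0; j < ok.size(); ++j) {
      if (ok[j] == EMPTY) continue;
      uint64_t i = mixHash(ok[j]) & mask;
      while (keys[i] != EMPTY) i = (i + 1) & mask;
      keys[i] = ok[j];
      vals[i] = ov[j];
    }
  }
};

struct GenomeIdx {
  int k = 0;
  OAMap<IndexEntry> map;
  std::vector<std::string> recNames;
  std::vector<double> recLens;
  double totalWindows = 0.0;
};

// candidate tag loci, kept packed (may hold ~genome-size entries)
struct CandSet {
  int k = 0;
  std::vector<uint64_t> code;
  std::vector<int32_t> rec;
  std::vector<uint32_t> pos;
  std::vector<std::string> recNames;
};

// unified tag+error membership map for counting; slots 0..nTag-1 are tags,
// nTag..nTag+nErr-1 are error k-mers
struct DbLookup {
  int k = 0;
  int nTag = 0;
  int nErr = 0;
  OAMap<int32_t> map;
};

// true iff no canonical word other than `code` itself (same k-mer family) and
// the optional `allow` word lies within Hamming distance 1 of `code` in idx
inline bool isolatedInIndex(uint64_t code, int k, const GenomeIdx& idx,
                            bool haveAllow, uint64_t allow) {
  for (int p = 0; p < k; ++p) {
    int shift = 2 * (k - 1 - p);
    uint64_t orig = (code >> shift) & 3ULL;
    uint64_t cleared = code & ~(3ULL << shift);
    for (uint64_t b = 0; b < 4; ++b) {
      if (b == orig) continue;
      uint64_t y = cleared | (b << shift);
      uint64_t cy = canonical(y, k);
      if (cy == code) continue;
      if (haveAllow && cy == allow) continue;
      if (idx.map.find(cy) != nullptr) return false;
    }
  }
  return true;
}

} // namespace kmerdepth

#endif
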