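#include <Rcpp.h>
#include <algorithm>
#include <set>
#include "kmer.h"

using namespace Rcpp;
using namespace kmerdepth;

static void checkK(int k) {
  if (k < 1 || k > 32)
    stop("k must be between 1 and 32 (k-mer must fit one 64-bit word)");
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) stop("NA k-mer string");
    const char* s = CHAR(seqs[i]);
    int k = (int)LENGTH(seqs[i]);
    checkK(k);
    uint64_t x;
    if (!encodeKmer(s, k, x))
      stop("invalid alphabet: k-mer '%s' contains a non-ACGT character", s);
    out[i] = decodeKmer(canonical(x, k), k);
  }
  return out;
}

// packed canonical code as a double; exact only for k <= 26 (checked in R)
// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) stop("NA k-mer string");
    const char* s = CHAR(seqs[i]);
    int k = (int)LENGTH(seqs[i]);
    checkK(k);
    uint64_t x;
    if (!encodeKmer(s, k, x))
      stop("invalid alphabet: k-mer '%s' contains a non-ACGT character", s);
    out[i] = (double)canonical(x, k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int k) {
  checkK(k);
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = codes[i];
    if (ISNAN(v) || v < 0) stop("k-mer codes must be non-negative numbers");
    out[i] = decodeKmer((uint64_t)v, k);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) stop("NA k-mer string");
    int ka = (int)LENGTH(a[i]), kb = (int)LENGTH(b[i]);
    if (ka != kb)
      stop("k-mer length mismatch (%d vs %d)", ka, kb);
    const char* sa = CHAR(a[i]);
    const char* sb = CHAR(b[i]);
    int d = 0;
    for (int j = 0; j < ka; ++j) {
      int ca = baseCode(sa[j]), cb = baseCode(sb[j]);
      if (ca < 0 || cb < 0) stop("invalid alphabet in k-mer");
      if (ca != cb) ++d;
    }
    out[i] = d;
  }
  return out;
}

// all canonical forms of the 3k single-substitution neighbors of x, excluding
// any neighbor that collapses onto x's own canonical form; sorted, unique
// [[Rcpp::export]]
CharacterVector cpp_neighbors(std::string x) {
  int k = (int)x.size();
  checkK(k);
  uint64_t code;
  if (!encodeKmer(x.c_str(), k, code))
    stop("invalid alphabet: k-mer '%s' contains a non-ACGT character", x.c_str());
  uint64_t cx = canonical(code, k);
  std::set<uint64_t> nb;
  for (int p = 0; p < k; ++p) {
    int shift = 2 * (k - 1 - p);
    uint64_t orig = (cx >> shift) & 3ULL;
    uint64_t cleared = cx & ~(3ULL << shift);
    for (uint64_t b = 0; b < 4; ++b) {
      if (b == orig) continue;
      uint64_t cy = canonical(cleared | (b << shift), k);
      if (cy != cx) nb.insert(cy);
    }
  }
  CharacterVector out(nb.size());
  R_xlen_t i = 0;
  for (uint64_t v : nb) out[i++] = decodeKmer(v, k);
  return out;
}

// [[Rcpp::export]]
List cpp_scan(CharacterVector seq, int k) {
  checkK(k);
  if (seq.size() != 1) stop("seq must be a single string");
  double nNucl = 0.0, nKmer = 0.0;
  std::vector<int> positions;
  std::vector<uint64_t> codes;
  if (seq[0] != NA_STRING) {
    const char* s = CHAR(seq[0]);
    size_t n = (size_t)LENGTH(seq[0]);
    scanString(s, n, k, nNucl, nKmer, [&](size_t pos, uint64_t c) {
      positions.push_back((int)pos);
      codes.push_back(c);
    });
  }
  R_xlen_t m = (R_xlen_t)codes.size();
  CharacterVector kmers(m);
  for (R_xlen_t i = 0; i < m; ++i) kmers[i] = decodeKmer(codes[(size_t)i], k);
  return List::create(_["position"] = wrap(positions),
                      _["kmer"] = kmers,
                      _["n_nucl"] = nNucl,
                      _["n_kmer"] = nKmer);
}

// FNV-1a over k and the tag/error k-mer strings; database fingerprint used to
// refuse merging counts that came from different databases
// [[Rcpp::export]]
std::string cpp_db_hash(CharacterVector tags, CharacterVector errs, int k) {
  uint64_t h = 1469598103934665603ULL;
  auto mix = [&h](const char* s, size_t n) {
    for (size_t i = 0; i < n; ++i) {
      h ^= (uint64_t)(unsigned char)s[i];
      h *= 1099511628211ULL;
    }
    h ^= (uint64_t)'|';
    h *= 1099511628211ULL;
  };
  char kb[16];
  snprintf(kb, sizeof(kb), "k=%d", k);
  mix(kb, strlen(kb));
  for (R_xlen_t i = 0; i < tags.size(); ++i) mix(CHAR(tags[i]), (size_t)LENGTH(tags[i]));
  mix("#", 1);
  for (R_xlen_t i = 0; i < errs.size(); ++i) mix(CHAR(errs[i]), (size_t)LENGTH(errs[i]));
  char buf[24];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
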