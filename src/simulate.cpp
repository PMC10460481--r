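#include <Rcpp.h>
#include "kmer.h"

using namespace Rcpp;
using namespace kmerdepth;

// i.i.d. uniform ACGT sequence (R RNG)
// [[Rcpp::export]]
CharacterVector cpp_random_genome(double length) {
  if (length < 1) stop("genome length must be >= 1");
  size_t n = (size_t)length;
  std::string s(n, 'A');
  for (size_t i = 0; i < n; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    s[i] = BASES[b];
  }
  return CharacterVector::create(s);
}

// replace every non-ACGT character with a uniform random base (R RNG)
// [[Rcpp::export]]
CharacterVector cpp_sanitize(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) stop("NA sequence");
    std::string s(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]));
    for (size_t j = 0; j < s.size(); ++j) {
      if (baseCode(s[j]) < 0) {
        int b = (int)(unif_rand() * 4.0);
        if (b > 3) b = 3;
        s[j] = BASES[b];
      }
    }
    out[i] = s;
  }
  return out;
}

// uniform fixed-length reads from a single sequence, both strands; per base,
// mutually exclusive events: -> N w.p. pN, -> one of the 3 other bases w.p.
// pSub, else unchanged (R RNG)
// [[Rcpp::export]]
List cpp_simulate_reads(CharacterVector genome, int nReads, int readLen,
                        double pN, double pSub) {
  if (genome.size() != 1 || genome[0] == NA_STRING) stop("genome must be a single string");
  if (readLen < 1) stop("readLen must be >= 1");
  if (pN < 0 || pSub < 0 || pN + pSub > 1) stop("need pN, pSub >= 0 and pN + pSub <= 1");
  const char* g = CHAR(genome[0]);
  R_xlen_t L = (R_xlen_t)LENGTH(genome[0]);
  if (L < readLen) stop("genome length (%ld) shorter than read length (%d)", (long)L, readLen);
  if (nReads < 0) nReads = 0;
  CharacterVector reads(nReads);
  IntegerVector start(nReads), strand(nReads);
  std::string buf((size_t)readLen, 'A');
  double nStarts = (double)(L - readLen + 1);
  for (int r = 0; r < nReads; ++r) {
    R_xlen_t s0 = (R_xlen_t)(unif_rand() * nStarts);
    if (s0 > L - readLen) s0 = L - readLen;
    int rev = (unif_rand() < 0.5) ? 0 : 1;
    if (!rev) {
      for (int i = 0; i < readLen; ++i) buf[(size_t)i] = g[s0 + i];
    } else {
      for (int i = 0; i < readLen; ++i)
        buf[(size_t)i] = complementChar(g[s0 + readLen - 1 - i]);
    }
    for (int i = 0; i < readLen; ++i) {
      double u = unif_rand();
      if (u < pN) {
        buf[(size_t)i] = 'N';
      } else if (u < pN + pSub) {
        int c = baseCode(buf[(size_t)i]);
        if (c >= 0) {
          int j = (int)(unif_rand() * 3.0);
          if (j > 2) j = 2;
          buf[(size_t)i] = BASES[(c + 1 + j) & 3];
        }
      }
    }
    reads[r] = buf;
    start[r] = (int)s0;
    strand[r] = rev;
  }
  return List::create(_["read"] = reads, _["start"] = start, _["strand"] = strand);
}
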