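#include <Rcpp.h>
#include "kmer.h"

using namespace Rcpp;
using namespace kmerdepth;

// [[Rcpp::export]]
SEXP cpp_make_lookup(CharacterVector tags, CharacterVector errs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  DbLookup* lk = new DbLookup();
  lk->k = k;
  lk->nTag = (int)tags.size();
  lk->nErr = (int)errs.size();
  lk->map.init((double)(tags.size() + errs.size()));
  for (R_xlen_t i = 0; i < tags.size(); ++i) {
    uint64_t x;
    if ((int)LENGTH(tags[i]) != k) stop("tag k-mer length != k");
    if (!encodeKmer(CHAR(tags[i]), k, x))
      stop("invalid alphabet in tag k-mer '%s'", CHAR(tags[i]));
    auto res = lk->map.emplace(canonical(x, k));
    if (!res.second) stop("duplicated tag k-mer '%s'", CHAR(tags[i]));
    *res.first = (int32_t)i;
  }
  for (R_xlen_t i = 0; i < errs.size(); ++i) {
    uint64_t x;
    if ((int)LENGTH(errs[i]) != k) stop("error k-mer length != k");
    if (!encodeKmer(CHAR(errs[i]), k, x))
      stop("invalid alphabet in error k-mer '%s'", CHAR(errs[i]));
    auto res = lk->map.emplace(canonical(x, k));
    if (!res.second)
      stop("error k-mer '%s' collides with another database k-mer", CHAR(errs[i]));
    *res.first = (int32_t)(lk->nTag + i);
  }
  XPtr<DbLookup> ptr(lk, true);
  return ptr;
}

// every ACGT-only window of every read is looked up against the tag+error set;
// matches increment per-k-mer counts; all bases (including N) count in n_nucl
// [[Rcpp::export]]
List cpp_count_reads(SEXP xp, CharacterVector reads) {
  XPtr<DbLookup> lk(xp);
  int k = lk->k;
  NumericVector tagCounts(lk->nTag), errCounts(lk->nErr);
  double* tc = REAL(tagCounts);
  double* ec = REAL(errCounts);
  double nNucl = 0.0, nKmer = 0.0;
  const auto& map = lk->map;
  int nTag = lk->nTag;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) stop("NA read sequence at record %ld", (long)(r + 1));
    const char* s = CHAR(reads[r]);
    size_t n = (size_t)LENGTH(reads[r]);
    scanString(s, n, k, nNucl, nKmer, [&](size_t, uint64_t code) {
      const int32_t* slot = map.find(code);
      if (slot != nullptr) {
        if (*slot < nTag) tc[*slot] += 1.0; else ec[*slot - nTag] += 1.0;
      }
    });
  }
  return List::create(_["tag_counts"] = tagCounts,
                      _["err_counts"] = errCounts,
                      _["n_nucl"] = nNucl,
                      _["n_kmer"] = nKmer,
                      _["n_reads"] = (double)reads.size());
}
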