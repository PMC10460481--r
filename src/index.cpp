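#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <unordered_set>
#include "kmer.h"

using namespace Rcpp;
using namespace kmerdepth;

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  if (seqs.size() < 1) stop("empty genome: no FASTA records");
  if (seqs.size() != names.size()) stop("seqs/names length mismatch");
  GenomeIdx* idx = new GenomeIdx();
  idx->k = k;
  double totalLen = 0.0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) totalLen += (double)LENGTH(seqs[i]);
  // distinct k-mers are bounded by the window count; random input is nearly
  // all-distinct, so size the table for it once and avoid growth
  idx->map.init(totalLen);
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(seqs[r]);
    size_t n = (size_t)LENGTH(seqs[r]);
    idx->recNames.push_back(std::string(CHAR(names[r])));
    idx->recLens.push_back((double)n);
    double nn = 0.0, nk = 0.0;
    scanString(s, n, k, nn, nk, [&](size_t pos, uint64_t code) {
      auto res = idx->map.emplace(code);
      if (res.second)
        *res.first = IndexEntry{1u, (int32_t)r, (uint32_t)pos};
      else
        res.first->count++;
    });
    idx->totalWindows += nk;
  }
  XPtr<GenomeIdx> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<GenomeIdx> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_distinct"] = (double)idx->map.n,
                      _["n_windows"] = idx->totalWindows,
                      _["record_names"] = wrap(idx->recNames),
                      _["record_lengths"] = wrap(idx->recLens));
}

// [[Rcpp::export]]
NumericVector cpp_index_count(SEXP xp, CharacterVector kmers) {
  XPtr<GenomeIdx> idx(xp);
  int k = idx->k;
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) stop("NA k-mer string");
    if ((int)LENGTH(kmers[i]) != k)
      stop("query k-mer length %d does not match index k=%d", (int)LENGTH(kmers[i]), k);
    uint64_t x;
    if (!encodeKmer(CHAR(kmers[i]), k, x))
      stop("invalid alphabet in query k-mer '%s'", CHAR(kmers[i]));
    const IndexEntry* e = idx->map.find(canonical(x, k));
    out[i] = (e == nullptr) ? 0.0 : (double)e->count;
  }
  return out;
}

// full table of the index, sorted by (record, position); intended for small
// genomes (tests/inspection) - materializes one string per distinct k-mer
// [[Rcpp::export]]
DataFrame cpp_index_dump(SEXP xp) {
  XPtr<GenomeIdx> idx(xp);
  size_t n = idx->map.n;
  std::vector<std::pair<uint64_t, IndexEntry>> entries;
  entries.reserve(n);
  for (size_t s = 0; s < idx->map.capacity(); ++s) {
    if (idx->map.keys[s] == OAMap<IndexEntry>::EMPTY) continue;
    entries.push_back({idx->map.keys[s], idx->map.vals[s]});
  }
  std::sort(entries.begin(), entries.end(),
            [](const std::pair<uint64_t, IndexEntry>& a,
               const std::pair<uint64_t, IndexEntry>& b) {
              if (a.second.rec != b.second.rec) return a.second.rec < b.second.rec;
              return a.second.pos < b.second.pos;
            });
  CharacterVector kmer(n), record(n);
  IntegerVector position(n);
  NumericVector count(n);
  for (size_t i = 0; i < n; ++i) {
    kmer[i] = decodeKmer(entries[i].first, idx->k);
    record[i] = idx->recNames[(size_t)entries[i].second.rec];
    position[i] = (int)entries[i].second.pos;
    count[i] = (double)entries[i].second.count;
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["record"] = record, _["position"] = position,
                           _["stringsAsFactors"] = false);
}

struct CandRow {
  uint64_t code;
  int32_t rec;
  uint32_t pos;
};

// k-mers with count 1 in the primary index and count 1 in every other index,
// each carrying its unique primary-genome locus; sorted by (record, position)
// [[Rcpp::export]]
SEXP cpp_select_unique(SEXP xp, List others) {
  XPtr<GenomeIdx> idx(xp);
  std::vector<GenomeIdx*> oidx;
  for (R_xlen_t i = 0; i < others.size(); ++i) {
    XPtr<GenomeIdx> o(as<SEXP>(others[i]));
    if (o->k != idx->k)
      stop("k mismatch between genome indexes (%d vs %d)", o->k, idx->k);
    oidx.push_back(o.get());
  }
  std::vector<CandRow> rows;
  rows.reserve(idx->map.n);
  for (size_t s = 0; s < idx->map.capacity(); ++s) {
    if (idx->map.keys[s] == OAMap<IndexEntry>::EMPTY) continue;
    const IndexEntry& e = idx->map.vals[s];
    if (e.count != 1u) continue;
    bool ok = true;
    for (GenomeIdx* o : oidx) {
      const IndexEntry* oe = o->map.find(idx->map.keys[s]);
      if (oe == nullptr || oe->count != 1u) { ok = false; break; }
    }
    if (!ok) continue;
    rows.push_back(CandRow{idx->map.keys[s], e.rec, e.pos});
  }
  std::sort(rows.begin(), rows.end(), [](const CandRow& a, const CandRow& b) {
    if (a.rec != b.rec) return a.rec < b.rec;
    return a.pos < b.pos;
  });
  CandSet* cs = new CandSet();
  cs->k = idx->k;
  cs->recNames = idx->recNames;
  size_t n = rows.size();
  cs->code.resize(n);
  cs->rec.resize(n);
  cs->pos.resize(n);
  for (size_t i = 0; i < n; ++i) {
    cs->code[i] = rows[i].code;
    cs->rec[i] = rows[i].rec;
    cs->pos[i] = rows[i].pos;
  }
  XPtr<CandSet> ptr(cs, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_cand_info(SEXP xp) {
  XPtr<CandSet> cs(xp);
  return List::create(_["k"] = cs->k, _["n"] = (double)cs->code.size());
}

// [[Rcpp::export]]
DataFrame cpp_cand_df(SEXP xp) {
  XPtr<CandSet> cs(xp);
  size_t n = cs->code.size();
  CharacterVector kmer(n), record(n);
  IntegerVector position(n);
  for (size_t i = 0; i < n; ++i) {
    kmer[i] = decodeKmer(cs->code[i], cs->k);
    record[i] = cs->recNames[(size_t)cs->rec[i]];
    position[i] = (int)cs->pos[i];
  }
  return DataFrame::create(_["kmer"] = kmer, _["record"] = record,
                           _["position"] = position,
                           _["stringsAsFactors"] = false);
}

// keep candidates none of whose 3k single-mismatch neighbors occur in the
// primary index (Hamming isolation >= 2 from every other genomic k-mer)
// [[Rcpp::export]]
SEXP cpp_filter_isolated(SEXP cxp, SEXP ixp) {
  XPtr<CandSet> cs(cxp);
  XPtr<GenomeIdx> idx(ixp);
  if (cs->k != idx->k) stop("k mismatch between candidates and index");
  CandSet* out = new CandSet();
  out->k = cs->k;
  out->recNames = cs->recNames;
  size_t n = cs->code.size();
  for (size_t i = 0; i < n; ++i) {
    if (isolatedInIndex(cs->code[i], cs->k, *idx, false, 0)) {
      out->code.push_back(cs->code[i]);
      out->rec.push_back(cs->rec[i]);
      out->pos.push_back(cs->pos[i]);
    }
  }
  XPtr<CandSet> ptr(out, true);
  return ptr;
}

static DataFrame tagsToDf(const CandSet& cs,
                          const std::vector<size_t>& keep) {
  size_t n = keep.size();
  CharacterVector kmer(n), record(n);
  IntegerVector position(n), window1mb(n);
  for (size_t i = 0; i < n; ++i) {
    size_t j = keep[i];
    kmer[i] = decodeKmer(cs.code[j], cs.k);
    record[i] = cs.recNames[(size_t)cs.rec[j]];
    position[i] = (int)cs.pos[j];
    window1mb[i] = (int)(cs.pos[j] / 1000000u);
  }
  return DataFrame::create(_["kmer"] = kmer, _["record"] = record,
                           _["position"] = position,
                           _["window_1mb"] = window1mb,
                           _["stringsAsFactors"] = false);
}

// partition each record into `windowLen`-bp windows; only windows whose index
// is divisible by `keepEvery` contribute, and each contributes its leftmost
// candidate
// [[Rcpp::export]]
DataFrame cpp_filter_spacing(SEXP cxp, int windowLen, int keepEvery) {
  XPtr<CandSet> cs(cxp);
  if (windowLen < 1 || keepEvery < 1) stop("windowLen and keepEvery must be >= 1");
  std::vector<size_t> keep;
  int32_t lastRec = -1;
  int64_t lastWin = -1;
  size_t n = cs->code.size();
  for (size_t i = 0; i < n; ++i) {
    int64_t win = (int64_t)(cs->pos[i] / (uint32_t)windowLen);
    if (win % keepEvery != 0) continue;
    if (cs->rec[i] == lastRec && win == lastWin) continue;  // leftmost already kept
    keep.push_back(i);
    lastRec = cs->rec[i];
    lastWin = win;
  }
  return tagsToDf(*cs, keep);
}

// spacing-aware isolation: equivalent to cpp_filter_spacing(cpp_filter_isolated(.))
// but only tests candidates inside eligible windows, left to right, stopping at
// the first survivor per window
// [[Rcpp::export]]
DataFrame cpp_build_tags_lazy(SEXP cxp, SEXP ixp, int windowLen, int keepEvery) {
  XPtr<CandSet> cs(cxp);
  XPtr<GenomeIdx> idx(ixp);
  if (cs->k != idx->k) stop("k mismatch between candidates and index");
  if (windowLen < 1 || keepEvery < 1) stop("windowLen and keepEvery must be >= 1");
  std::vector<size_t> keep;
  int32_t lastRec = -1;
  int64_t lastWin = -1;
  size_t n = cs->code.size();
  for (size_t i = 0; i < n; ++i) {
    int64_t win = (int64_t)(cs->pos[i] / (uint32_t)windowLen);
    if (win % keepEvery != 0) continue;
    if (cs->rec[i] == lastRec && win == lastWin) continue;
    if (!isolatedInIndex(cs->code[i], cs->k, *idx, false, 0)) continue;
    keep.push_back(i);
    lastRec = cs->rec[i];
    lastWin = win;
  }
  return tagsToDf(*cs, keep);
}

// up to nVariants distinct single-mismatch variants per tag, drawn uniformly
// without replacement from the 3k possibilities (R RNG); a variant is kept iff
// absent from the genome, no non-parent genomic k-mer within distance 1, and
// not colliding with a previously accepted error k-mer
// [[Rcpp::export]]
DataFrame cpp_gen_errors(CharacterVector tagKmers, SEXP ixp, int nVariants) {
  XPtr<GenomeIdx> idx(ixp);
  int k = idx->k;
  if (nVariants < 1) stop("nVariants must be >= 1");
  std::unordered_set<uint64_t> accepted;
  std::vector<std::string> vKmer, vParent;
  std::vector<int> vPos;
  std::vector<char> vBase;
  int nAlt = 3 * k;
  std::vector<int> slots((size_t)nAlt);
  for (R_xlen_t t = 0; t < tagKmers.size(); ++t) {
    const char* s = CHAR(tagKmers[t]);
    if ((int)LENGTH(tagKmers[t]) != k)
      stop("tag k-mer length does not match index k=%d", k);
    uint64_t pc;
    if (!encodeKmer(s, k, pc))
      stop("invalid alphabet in tag k-mer '%s'", s);
    pc = canonical(pc, k);
    std::string parent = decodeKmer(pc, k);
    for (int i = 0; i < nAlt; ++i) slots[(size_t)i] = i;
    int got = 0;
    for (int i = 0; i < nAlt && got < nVariants; ++i) {
      // partial Fisher-Yates: uniform draw without replacement
      int j = i + (int)(unif_rand() * (double)(nAlt - i));
      if (j >= nAlt) j = nAlt - 1;
      std::swap(slots[(size_t)i], slots[(size_t)j]);
      int slot = slots[(size_t)i];
      int p = slot / 3;
      int shift = 2 * (k - 1 - p);
      uint64_t orig = (pc >> shift) & 3ULL;
      uint64_t b = ((uint64_t)(slot % 3) + orig + 1ULL) & 3ULL;
      uint64_t raw = (pc & ~(3ULL << shift)) | (b << shift);
      uint64_t v = canonical(raw, k);
      if (idx->map.find(v) != nullptr) continue;                 // genomic
      if (accepted.find(v) != accepted.end()) continue;          // collision
      if (!isolatedInIndex(v, k, *idx, true, pc)) continue;      // non-parent neighbor
      accepted.insert(v);
      vKmer.push_back(decodeKmer(v, k));
      vParent.push_back(parent);
      vPos.push_back(p);
      vBase.push_back(BASES[b]);
      ++got;
    }
  }
  size_t n = vKmer.size();
  CharacterVector kmer(n), parentv(n), base(n);
  IntegerVector mmpos(n);
  for (size_t i = 0; i < n; ++i) {
    kmer[i] = vKmer[i];
    parentv[i] = vParent[i];
    mmpos[i] = vPos[i];
    base[i] = std::string(1, vBase[i]);
  }
  return DataFrame::create(_["kmer"] = kmer, _["parent"] = parentv,
                           _["mm_pos"] = mmpos, _["mm_base"] = base,
                           _["stringsAsFactors"] = false);
}
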