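// Exact/k-mismatch short-read mapping core.
//
// A sorted (k-mer code, packed location) table over the forward strand of all
// contigs serves as the seed index; reads are verified end-to-end against the
// reference with a per-mate mismatch cap.  Only substitutions are modelled:
// candidate placements come from exact seed k-mers at fixed offsets, so a
// read maps as long as at least one of its seeds is error-free.  For exact
// (zero-mismatch) search the offset-0 seed guarantees completeness.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;                   // uppercase contig sequence
  std::vector<std::pair<uint64_t, uint64_t> > tab; // (code, contig<<40 | pos), sorted
};

// encode k-mer starting at position i; returns false if any base invalid
static inline bool encode_kmer(const std::string& s, size_t i, int k, uint64_t& code) {
  code = 0;
  for (int j = 0; j < k; ++j) {
    int b = base_code(s[i + j]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export]]
SEXP hd_cpp_index_build(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  size_t total = 0;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) total += LENGTH(STRING_ELT(seqs, c));
  idx->tab.reserve(total);
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    idx->seqs.push_back(s);
    if ((int)s.size() < k) continue;
    // rolling encode with validity run-length
    uint64_t code = 0;
    uint64_t mask = (k == 31) ? 0x3FFFFFFFFFFFFFFFULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t pos = i + 1 - (size_t)k;
        idx->tab.push_back(std::make_pair(code, ((uint64_t)c << 40) | pos));
      }
    }
  }
  std::sort(idx->tab.begin(), idx->tab.end());
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List hd_cpp_index_stats(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["n_kmers"] = (double)idx->tab.size(),
                      _["n_contigs"] = (int)idx->seqs.size());
}

static void lookup_code(const KmerIndex* idx, uint64_t code,
                        std::vector<uint64_t>& out) {
  std::pair<uint64_t, uint64_t> lo(code, 0);
  std::pair<uint64_t, uint64_t> hi(code, ~0ULL);
  std::vector<std::pair<uint64_t, uint64_t> >::const_iterator a =
      std::lower_bound(idx->tab.begin(), idx->tab.end(), lo);
  std::vector<std::pair<uint64_t, uint64_t> >::const_iterator b =
      std::upper_bound(idx->tab.begin(), idx->tab.end(), hi);
  for (; a != b; ++a) out.push_back(a->second);
}

// [[Rcpp::export]]
DataFrame hd_cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  std::vector<int> contig;
  std::vector<double> pos;
  std::vector<std::string> strand;
  uint64_t code;
  std::vector<uint64_t> hits;
  if (encode_kmer(kmer, 0, idx->k, code)) {
    lookup_code(idx.get(), code, hits);
    for (size_t i = 0; i < hits.size(); ++i) {
      contig.push_back((int)(hits[i] >> 40) + 1);
      pos.push_back((double)(hits[i] & 0xFFFFFFFFFFULL));
      strand.push_back("+");
    }
  }
  std::string rc = revcomp(kmer);
  if (rc != kmer && encode_kmer(rc, 0, idx->k, code)) {
    hits.clear();
    lookup_code(idx.get(), code, hits);
    for (size_t i = 0; i < hits.size(); ++i) {
      contig.push_back((int)(hits[i] >> 40) + 1);
      pos.push_back((double)(hits[i] & 0xFFFFFFFFFFULL));
      strand.push_back("-");
    }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

struct Hit {
  int contig;
  long long start;
  char strand;
  int mm;
};

static bool hit_less(const Hit& a, const Hit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.start != b.start) return a.start < b.start;
  return a.strand < b.strand;
}

// count mismatches of read vs contig at start, early exit beyond cap
static int verify(const std::string& ref, const std::string& read,
                  long long start, int cap) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char r = read[i], g = ref[start + i];
    int br = base_code(r), bg = base_code(g);
    if (br < 0 || bg < 0 || br != bg) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// all placements of `read` (already oriented) on the forward strands, mm <= cap
static void place_oriented(const KmerIndex* idx, const std::string& read,
                           char strand, int cap, std::vector<Hit>& out) {
  int k = idx->k;
  long long L = (long long)read.size();
  if (L < k) return;
  std::vector<long long> offs;
  for (long long o = 0; o + k <= L; o += k) offs.push_back(o);
  if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
  std::vector<std::pair<int, long long> > cand;
  uint64_t code;
  std::vector<uint64_t> hits;
  for (size_t oi = 0; oi < offs.size(); ++oi) {
    long long o = offs[oi];
    if (!encode_kmer(read, (size_t)o, k, code)) continue;
    hits.clear();
    lookup_code(idx, code, hits);
    for (size_t i = 0; i < hits.size(); ++i) {
      int c = (int)(hits[i] >> 40);
      long long p = (long long)(hits[i] & 0xFFFFFFFFFFULL);
      long long s = p - o;
      if (s < 0 || s + L > (long long)idx->seqs[c].size()) continue;
      cand.push_back(std::make_pair(c, s));
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (size_t i = 0; i < cand.size(); ++i) {
    int mm = verify(idx->seqs[cand[i].first], read, cand[i].second, cap);
    if (mm <= cap) {
      Hit h;
      h.contig = cand[i].first;
      h.start = cand[i].second;
      h.strand = strand;
      h.mm = mm;
      out.push_back(h);
    }
  }
}

static void place_read(const KmerIndex* idx, const std::string& read, int cap,
                       std::vector<Hit>& out) {
  place_oriented(idx, read, '+', cap, out);
  place_oriented(idx, revcomp(read), '-', cap, out);
}

// Fisher-Yates shuffle of equal-mismatch blocks using R's RNG, then stable
// order within the sorted frame: sort by key, then permute ties.
static void shuffle_ties(std::vector<int>& ord, const std::vector<int>& mm) {
  size_t i = 0;
  while (i < ord.size()) {
    size_t j = i + 1;
    while (j < ord.size() && mm[ord[j]] == mm[ord[i]]) ++j;
    for (size_t t = j - 1; t > i; --t) {
      size_t u = i + (size_t)(unif_rand() * (double)(t - i + 1));
      if (u > t) u = t;
      std::swap(ord[t], ord[i + (u - i)]);
    }
    i = j;
  }
}

// mode: 0 = report all (up to max_hits) sorted; 1 = best one, seeded tie-break
// [[Rcpp::export]]
DataFrame hd_cpp_map_single(SEXP xp, CharacterVector reads, int max_mm,
                            int max_hits, int mode) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> o_read, o_contig, o_mm;
  std::vector<double> o_start;
  std::vector<std::string> o_strand;
  RNGScope rng;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::vector<Hit> hits;
    place_read(idx.get(), rd, max_mm, hits);
    std::sort(hits.begin(), hits.end(), hit_less);
    size_t keep = hits.size();
    if (mode == 1) {
      if (!hits.empty()) {
        size_t nb = 1;
        while (nb < hits.size() && hits[nb].mm == hits[0].mm) ++nb;
        size_t pick = (size_t)(unif_rand() * (double)nb);
        if (pick >= nb) pick = nb - 1;
        std::swap(hits[0], hits[pick]);
        keep = 1;
      }
    } else if ((int)keep > max_hits) {
      keep = (size_t)max_hits;
    }
    for (size_t i = 0; i < keep; ++i) {
      o_read.push_back((int)r + 1);
      o_contig.push_back(hits[i].contig + 1);
      o_start.push_back((double)hits[i].start);
      o_strand.push_back(std::string(1, hits[i].strand));
      o_mm.push_back(hits[i].mm);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                           _["start"] = o_start, _["strand"] = o_strand,
                           _["mismatches"] = o_mm,
                           _["stringsAsFactors"] = false);
}

struct PairHit {
  int contig;
  long long s1, s2; // mate1, mate2 starts (0-based)
  char strand1;     // orientation of mate 1; pair orientation is always FR
  int mm;
};

static bool pairhit_less(const PairHit& a, const PairHit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.contig != b.contig) return a.contig < b.contig;
  long long ma = a.s1 < a.s2 ? a.s1 : a.s2;
  long long mb = b.s1 < b.s2 ? b.s1 : b.s2;
  if (ma != mb) return ma < mb;
  return a.strand1 < b.strand1;
}

// mode: 1 = best one (seeded tie-break), 2 = best k (max_place)
// [[Rcpp::export]]
DataFrame hd_cpp_map_pairs(SEXP xp, CharacterVector r1, CharacterVector r2,
                           int max_mm, double fmin, double fmax, int mode,
                           int max_place) {
  XPtr<KmerIndex> idx(xp);
  if (r1.size() != r2.size()) stop("mate vectors differ in length");
  std::vector<int> o_pair, o_contig, o_mm;
  std::vector<double> o_s1, o_e1, o_s2, o_e2;
  std::vector<std::string> o_strand1;
  RNGScope rng;
  for (R_xlen_t r = 0; r < r1.size(); ++r) {
    std::string a = as<std::string>(r1[r]);
    std::string b = as<std::string>(r2[r]);
    std::vector<Hit> h1, h2;
    place_read(idx.get(), a, max_mm, h1);
    place_read(idx.get(), b, max_mm, h2);
    std::vector<PairHit> combos;
    for (size_t i = 0; i < h1.size(); ++i) {
      for (size_t j = 0; j < h2.size(); ++j) {
        if (h1[i].contig != h2[j].contig) continue;
        if (h1[i].strand == h2[j].strand) continue; // FR requires opposite
        long long e1 = h1[i].start + (long long)a.size();
        long long e2 = h2[j].start + (long long)b.size();
        long long frag;
        if (h1[i].strand == '+') {
          // mate1 forward upstream, mate2 reverse downstream
          if (h2[j].start < h1[i].start) continue;
          frag = e2 - h1[i].start;
        } else {
          if (h1[i].start < h2[j].start) continue;
          frag = e1 - h2[j].start;
        }
        if ((double)frag < fmin || (double)frag > fmax) continue;
        PairHit ph;
        ph.contig = h1[i].contig;
        ph.s1 = h1[i].start;
        ph.s2 = h2[j].start;
        ph.strand1 = h1[i].strand;
        ph.mm = h1[i].mm + h2[j].mm;
        combos.push_back(ph);
      }
    }
    std::sort(combos.begin(), combos.end(), pairhit_less);
    combos.erase(std::unique(combos.begin(), combos.end(),
                             [](const PairHit& x, const PairHit& y) {
                               return x.contig == y.contig && x.s1 == y.s1 &&
                                      x.s2 == y.s2 && x.strand1 == y.strand1;
                             }),
                 combos.end());
    // seeded shuffle among equal-mismatch runs, then truncate
    std::vector<int> ord(combos.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::vector<int> mmv(combos.size());
    for (size_t i = 0; i < combos.size(); ++i) mmv[i] = combos[i].mm;
    shuffle_ties(ord, mmv);
    size_t keep = combos.size();
    if (mode == 1) keep = keep > 0 ? 1 : 0;
    else if ((int)keep > max_place) keep = (size_t)max_place;
    for (size_t i = 0; i < keep; ++i) {
      const PairHit& ph = combos[ord[i]];
      o_pair.push_back((int)r + 1);
      o_contig.push_back(ph.contig + 1);
      o_s1.push_back((double)ph.s1);
      o_e1.push_back((double)(ph.s1 + (long long)a.size()));
      o_s2.push_back((double)ph.s2);
      o_e2.push_back((double)(ph.s2 + (long long)b.size()));
      o_strand1.push_back(std::string(1, ph.strand1));
      o_mm.push_back(ph.mm);
    }
  }
  return DataFrame::create(_["pair"] = o_pair, _["contig"] = o_contig,
                           _["start1"] = o_s1, _["end1"] = o_e1,
                           _["start2"] = o_s2, _["end2"] = o_e2,
                           _["strand1"] = o_strand1, _["mismatches"] = o_mm,
                           _["stringsAsFactors"] = false);
}

// Anchors: k-mers unique within each sequence, shared between the two.
// Forward anchors match A and B directly; reverse anchors match A against
// the reverse complement of B (posB reported in B's forward coordinates).
static void unique_kmers(const std::string& s, int k,
                         std::unordered_map<uint64_t, long long>& out) {
  std::unordered_map<uint64_t, long long> seen;
  if ((int)s.size() < k) return;
  uint64_t code = 0;
  uint64_t mask = (k == 31) ? 0x3FFFFFFFFFFFFFFFULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      long long pos = (long long)(i + 1 - (size_t)k);
      std::unordered_map<uint64_t, long long>::iterator it = seen.find(code);
      if (it == seen.end()) seen[code] = pos;
      else it->second = -1; // repeated: not unique
    }
  }
  for (std::unordered_map<uint64_t, long long>::iterator it = seen.begin();
       it != seen.end(); ++it)
    if (it->second >= 0) out[it->first] = it->second;
}

// [[Rcpp::export]]
DataFrame hd_cpp_anchors(std::string a, std::string b, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, long long> ua, ub, ubrc;
  unique_kmers(a, k, ua);
  unique_kmers(b, k, ub);
  std::string brc = revcomp(b);
  unique_kmers(brc, k, ubrc);
  std::vector<double> posA, posB;
  std::vector<std::string> strand;
  for (std::unordered_map<uint64_t, long long>::iterator it = ua.begin();
       it != ua.end(); ++it) {
    std::unordered_map<uint64_t, long long>::iterator jb = ub.find(it->first);
    if (jb != ub.end()) {
      posA.push_back((double)it->second);
      posB.push_back((double)jb->second);
      strand.push_back("+");
    }
    std::unordered_map<uint64_t, long long>::iterator jr = ubrc.find(it->first);
    if (jr != ubrc.end()) {
      posA.push_back((double)it->second);
      posB.push_back((double)((long long)b.size() - k - jr->second));
      strand.push_back("-");
    }
  }
  return DataFrame::create(_["posA"] = posA, _["posB"] = posB,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
int hd_cpp_count_mismatch(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int x = base_code(a[i]), y = base_code(b[i]);
    if (x < 0 || y < 0 || x != y) ++mm;
  }
  return mm;
}

// [[Rcpp::export]]
std::string hd_cpp_revcomp(std::string s) { return revcomp(s); }
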