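#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T=3, N (or anything else) = 4.
// Code 4 mismatches everything, including itself.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline int comp_code(int b) { return b < 4 ? 3 - b : 4; }

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) r[v.size() - 1 - i] = comp_code(v[i]);
  return r;
}

// Ungapped match count of q against s[start, start+|q|), early exit once the
// remaining positions cannot reach min_matches.
static inline int window_matches(const std::vector<int>& q,
                                 const std::vector<int>& s,
                                 int start, int min_matches) {
  const int L = (int)q.size();
  int matches = 0;
  int budget = L - min_matches;  // allowed mismatches
  for (int t = 0; t < L; ++t) {
    int gb = s[start + t];
    if (gb < 4 && gb == q[t]) {
      ++matches;
    } else {
      if (--budget < 0) return -1;
    }
  }
  return matches >= min_matches ? matches : -1;
}

struct HitRows {
  std::vector<int> qid, sid, start, matches;
  std::vector<int> strand;  // 0 = '+', 1 = '-'
  void push(int q, int s, int st, int m, int str) {
    qid.push_back(q); sid.push_back(s); start.push_back(st);
    matches.push_back(m); strand.push_back(str);
  }
  DataFrame frame() const {
    CharacterVector str(strand.size());
    for (size_t i = 0; i < strand.size(); ++i) str[i] = strand[i] ? "-" : "+";
    return DataFrame::create(_["qid"] = qid, _["sid"] = sid,
                             _["start"] = start, _["matches"] = matches,
                             _["strand"] = str);
  }
};

// Full-scan oracle: every window on both strands of every sequence with
// >= min_matches ungapped matches. A '-' strand hit means the reverse
// complement of the genomic window matches the oligo.
// [[Rcpp::export]]
DataFrame cpp_brute_hits(CharacterVector oligos, CharacterVector seqs,
                         int min_matches) {
  std::vector<std::vector<int>> enc(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) enc[i] = encode(as<std::string>(seqs[i]));
  HitRows out;
  for (int qi = 0; qi < oligos.size(); ++qi) {
    std::vector<int> q = encode(as<std::string>(oligos[qi]));
    std::vector<int> qr = revcomp_codes(q);
    const int L = (int)q.size();
    for (int si = 0; si < (int)enc.size(); ++si) {
      const std::vector<int>& s = enc[si];
      if ((int)s.size() < L) continue;
      const int last = (int)s.size() - L;
      for (int p = 0; p <= last; ++p) {
        int m = window_matches(q, s, p, min_matches);
        if (m >= 0) out.push(qi + 1, si + 1, p, m, 0);
        m = window_matches(qr, s, p, min_matches);
        if (m >= 0) out.push(qi + 1, si + 1, p, m, 1);
      }
    }
  }
  return out.frame();
}

// ---- k-mer index --------------------------------------------------------

struct KmerIndex {
  int k;
  std::vector<std::vector<int>> seqs;  // encoded genome, forward strand
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->seqs.resize(seqs.size());
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  size_t n_pos = 0;
  for (int si = 0; si < seqs.size(); ++si) {
    idx->seqs[si] = encode(as<std::string>(seqs[si]));
    const std::vector<int>& s = idx->seqs[si];
    uint64_t h = 0;
    int run = 0;  // length of current N-free suffix
    for (int p = 0; p < (int)s.size(); ++p) {
      if (s[p] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)s[p]) & mask;
      if (++run >= k) {
        idx->map[h].push_back(std::make_pair(si, p - k + 1));
        ++n_pos;
      }
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  ptr.attr("n_positions") = (double)n_pos;
  return ptr;
}

// [[Rcpp::export]]
double cpp_index_size(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  size_t n = 0;
  for (auto& kv : idx->map) n += kv.second.size();
  return (double)n;
}

// Occurrence positions of one k-mer (forward strand of the indexed genome);
// returns a two-column matrix (sid, start), 1-based sid, 0-based start.
// [[Rcpp::export]]
IntegerMatrix cpp_index_lookup(SEXP ptr, std::string kmer) {
  XPtr<KmerIndex> idx(ptr);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index k");
  uint64_t h = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b > 3) return IntegerMatrix(0, 2);  // N never indexed
    h = (h << 2) | (uint64_t)b;
  }
  auto it = idx->map.find(h);
  if (it == idx->map.end()) return IntegerMatrix(0, 2);
  IntegerMatrix m((int)it->second.size(), 2);
  for (int i = 0; i < m.nrow(); ++i) {
    m(i, 0) = it->second[i].first + 1;
    m(i, 1) = it->second[i].second;
  }
  return m;
}

// Seed-and-extend: collect candidate placements from shared k-mer seeds at
// every offset of the oligo (and of its reverse complement for '-' strand
// hits), then verify each placement by exact ungapped comparison. With
// seed_mm = 1 every Hamming-distance-1 neighbor of each seed is also looked
// up (BLAST-style neighborhood words): a counting argument over the
// 45 - k + 1 seed windows then guarantees a triggering seed for any locus
// with at most 9 mismatches over a 45-mer at k = 8.
// [[Rcpp::export]]
DataFrame cpp_seed_hits(CharacterVector oligos, SEXP ptr, int min_matches,
                        int seed_mm = 1) {
  XPtr<KmerIndex> idx(ptr);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  HitRows out;
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> probes_h;
  for (int qi = 0; qi < oligos.size(); ++qi) {
    std::vector<int> fwd = encode(as<std::string>(oligos[qi]));
    const int L = (int)fwd.size();
    if (L < k) stop("oligo shorter than index k");
    std::vector<int> rev = revcomp_codes(fwd);
    seen.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& q = strand ? rev : fwd;
      uint64_t h = 0;
      int run = 0;
      for (int p = 0; p < L; ++p) {
        if (q[p] > 3) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)q[p]) & mask;
        if (++run < k) continue;
        probes_h.clear();
        probes_h.push_back(h);
        if (seed_mm >= 1) {
          for (int pos = 0; pos < k; ++pos) {
            const int shift = 2 * (k - 1 - pos);
            const uint64_t cur = (h >> shift) & 3ULL;
            for (uint64_t nb = 0; nb < 4; ++nb) {
              if (nb == cur) continue;
              probes_h.push_back((h & ~(3ULL << shift)) | (nb << shift));
            }
          }
        }
        const int off = p - k + 1;  // seed offset within the oligo
        for (uint64_t ph : probes_h) {
          auto it = idx->map.find(ph);
          if (it == idx->map.end()) continue;
          for (auto& sp : it->second) {
            const int si = sp.first;
            const int cand = sp.second - off;
            if (cand < 0 || cand + L > (int)idx->seqs[si].size()) continue;
            uint64_t key = ((uint64_t)si << 33) | ((uint64_t)strand << 32) |
                           (uint64_t)(uint32_t)cand;
            if (!seen.insert(key).second) continue;
            int m = window_matches(q, idx->seqs[si], cand, min_matches);
            if (m >= 0) out.push(qi + 1, si + 1, cand, m, strand);
          }
        }
      }
    }
  }
  return out.frame();
}

// ---- hairpin screening --------------------------------------------------

// Nearest-neighbor Tm of an encoded subsequence under unimolecular
// conditions (no strand-concentration term): used for hairpin stems.
static double stem_tm(const std::vector<int>& s, int start, int len,
                      const double* dH, const double* dS,
                      double initH_AT, double initS_AT,
                      double initH_GC, double initS_GC,
                      double symS, double salt_per_pair) {
  double H = 0.0, S = 0.0;
  for (int t = 0; t < len - 1; ++t) {
    int code = 4 * s[start + t] + s[start + t + 1];
    H += dH[code];
    S += dS[code];
  }
  int b0 = s[start], b1 = s[start + len - 1];
  H += (b0 == 0 || b0 == 3) ? initH_AT : initH_GC;
  S += (b0 == 0 || b0 == 3) ? initS_AT : initS_GC;
  H += (b1 == 0 || b1 == 3) ? initH_AT : initH_GC;
  S += (b1 == 0 || b1 == 3) ? initS_AT : initS_GC;
  bool selfcomp = true;
  for (int t = 0; t < len; ++t)
    if (s[start + t] != comp_code(s[start + len - 1 - t])) { selfcomp = false; break; }
  if (selfcomp) S += symS;
  S += salt_per_pair * (len - 1);
  return 1000.0 * H / S - 273.15;
}

// Maximum unimolecular NN Tm over every ungapped stem (i, j, k):
// seq[i..i+k) reverse-complementary to seq[j..j+k), loop j-(i+k) >= min_loop,
// k >= min_stem. NA when no stem exists. Enumeration is by outermost paired
// position (p, q) with inward extension, which visits every (i, j, k) once.
// [[Rcpp::export]]
NumericVector cpp_hairpin_tm(CharacterVector seqs, int min_stem, int min_loop,
                             NumericVector dH, NumericVector dS,
                             NumericVector init_AT, NumericVector init_GC,
                             double sym_dS, double salt_per_pair) {
  if (dH.size() != 16 || dS.size() != 16)
    stop("dH and dS must have 16 entries (AA, AC, ..., TT order)");
  NumericVector out(seqs.size(), NA_REAL);
  for (int i = 0; i < seqs.size(); ++i) {
    std::vector<int> s = encode(as<std::string>(seqs[i]));
    const int n = (int)s.size();
    double best = NA_REAL;
    for (int p = 0; p < n; ++p) {
      for (int q = p + 2 * min_stem + min_loop - 1; q < n; ++q) {
        // extend paired run inward from outer pair (p, q)
        int m = 0;
        while (p + m < q - m && s[p + m] < 4 &&
               s[p + m] == comp_code(s[q - m])) ++m;
        if (m < min_stem) continue;
        int kmax = std::min(m, (q - p + 1 - min_loop) / 2);
        for (int k = min_stem; k <= kmax; ++k) {
          double tm = stem_tm(s, p, k, REAL(dH), REAL(dS),
                              init_AT[0], init_AT[1], init_GC[0], init_GC[1],
                              sym_dS, salt_per_pair);
          if (!R_finite(best) || tm > best) best = tm;
        }
      }
    }
    out[i] = best;
  }
  return out;
}
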