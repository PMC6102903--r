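// Seed-and-extend local alignment engine.
//
// A k-mer index over reference entries (plus strand only) is queried with
// exact k-mer seeds; seeds sharing an entry are clustered by diagonal and
// each cluster is extended with a banded affine-gap Smith-Waterman.
// Minus-strand nucleotide hits are found by searching the reverse
// complement of the query; coordinates are reported on the forward query
// with subject_start > subject_end marking the minus strand.
//
// Gap scoring: a gap of length L scores gap_open + L * gap_extend
// (both penalties are negative), matching the Gotoh convention used by
// classical pairwise aligners.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

struct KIndex {
  int k;
  bool is_nt;
  std::vector<std::string> seqs;  // uppercased
  std::vector<std::string> acc;
  long long ndb;                  // total residues
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > pos;
};

static inline char upc(char c) {
  return (c >= 'a' && c <= 'z') ? (char)(c - 'a' + 'A') : c;
}

// residue code for k-mer packing; -1 = breaks a seed window
static inline int chcode(char c, bool is_nt) {
  c = upc(c);
  if (is_nt) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
  }
  if (c < 'A' || c > 'Z' || c == 'X') return -1;  // X/ambiguous never seeds
  return c - 'A';
}

// residues that can ever count as a match
static inline bool alignable(char c, bool is_nt) {
  c = upc(c);
  if (is_nt) return c == 'A' || c == 'C' || c == 'G' || c == 'T';
  return c >= 'A' && c <= 'Z' && c != 'X';
}

static inline bool is_match(char a, char b, bool is_nt) {
  return upc(a) == upc(b) && alignable(a, is_nt);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (upc(r[i])) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: r[i] = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector acc, int k,
                     bool is_nt) {
  if (k < 2 || k > 12) stop("word size k must be in [2, 12]");
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->is_nt = is_nt;
  idx->ndb = 0;
  int n = seqs.size();
  idx->seqs.reserve(n);
  idx->acc.reserve(n);
  for (int e = 0; e < n; ++e) {
    std::string s = as<std::string>(seqs[e]);
    for (size_t i = 0; i < s.size(); ++i) s[i] = upc(s[i]);
    idx->seqs.push_back(s);
    idx->acc.push_back(as<std::string>(acc[e]));
    idx->ndb += (long long)s.size();
    int L = (int)s.size();
    if (L < k) continue;  // caller warns about skipped entries
    uint64_t key = 0, mask = (k >= 13) ? ~0ULL : ((1ULL << (5 * k)) - 1);
    int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = chcode(s[i], is_nt);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 5) | (uint64_t)c) & mask;
      if (++run >= k)
        idx->pos[key].push_back(std::make_pair((int32_t)e,
                                               (int32_t)(i - k + 1)));
    }
  }
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP ptr) {
  XPtr<KIndex> idx(ptr);
  return List::create(_["k"] = idx->k, _["n_entries"] = (int)idx->seqs.size(),
                      _["ndb"] = (double)idx->ndb,
                      _["n_kmers"] = (double)idx->pos.size(),
                      _["is_nt"] = idx->is_nt);
}

// [[Rcpp::export]]
List cpp_index_positions(SEXP ptr, std::string kmer) {
  // exact-position lookup for one k-mer (diagnostics / tests)
  XPtr<KIndex> idx(ptr);
  uint64_t key = 0;
  if ((int)kmer.size() != idx->k) stop("k-mer length mismatch");
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = chcode(kmer[i], idx->is_nt);
    if (c < 0) return List::create(_["entry"] = IntegerVector(0),
                                   _["offset"] = IntegerVector(0));
    key = (key << 5) | (uint64_t)c;
  }
  std::unordered_map<uint64_t,
    std::vector<std::pair<int32_t,int32_t> > >::const_iterator it =
      idx->pos.find(key);
  std::vector<int> es, os;
  if (it != idx->pos.end()) {
    for (size_t i = 0; i < it->second.size(); ++i) {
      es.push_back(it->second[i].first + 1);   // 1-based entry index
      os.push_back(it->second[i].second);      // 0-based offset
    }
  }
  return List::create(_["entry"] = wrap(es), _["offset"] = wrap(os));
}

struct Aln {
  int score, matches, mismatches, gapopens, columns;
  int qs, qe, ss, se;  // 1-based inclusive on the searched orientation
  bool ok;
};

// banded affine local alignment restricted to diagonals [dlo, dhi]
// (diag = j - i with 1-based i over query, j over subject)
static Aln band_align(const std::string& q, const std::string& s,
                      int dlo, int dhi, int match, int mismatch,
                      int gap_open, int gap_extend, bool is_nt,
                      std::vector<int>& H, std::vector<int>& E,
                      std::vector<int>& F, std::vector<uint8_t>& pH,
                      std::vector<uint8_t>& pE, std::vector<uint8_t>& pF) {
  int m = (int)q.size(), n = (int)s.size();
  int W = dhi - dlo + 1;
  size_t need = (size_t)(m + 1) * W;
  if (H.size() < need) {
    H.resize(need); E.resize(need); F.resize(need);
    pH.resize(need); pE.resize(need); pF.resize(need);
  }
  for (int c = 0; c < W; ++c) { H[c] = 0; E[c] = NEG_INF; F[c] = NEG_INF; }
  int best = 0, bi = -1, bc = -1;
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * W, prev = (size_t)(i - 1) * W;
    int clo = std::max(0, 1 - i - dlo);
    int chi = std::min(W - 1, n - i - dlo);
    for (int c = 0; c < W; ++c) { H[row + c] = 0; E[row + c] = NEG_INF;
                                  F[row + c] = NEG_INF; pH[row + c] = 0; }
    for (int c = clo; c <= chi; ++c) {
      int j = i + dlo + c;
      // E: gap in query (consume subject), from (i, c-1)
      int e = NEG_INF; uint8_t pe = 0;
      if (c - 1 >= clo) {
        int open = H[row + c - 1] + gap_open + gap_extend;
        int ext  = E[row + c - 1] + gap_extend;
        if (ext > open) { e = ext; pe = 1; } else { e = open; pe = 0; }
      }
      // F: gap in subject (consume query), from (i-1, c+1)
      int f = NEG_INF; uint8_t pf = 0;
      if (c + 1 < W && i - 1 >= 1) {
        int jprev = (i - 1) + dlo + (c + 1);
        if (jprev >= 1 && jprev <= n) {
          int open = H[prev + c + 1] + gap_open + gap_extend;
          int ext  = F[prev + c + 1] + gap_extend;
          if (ext > open) { f = ext; pf = 1; } else { f = open; pf = 0; }
        }
      }
      // diagonal from (i-1, c)
      int hd = 0; bool cont = false;
      if (i - 1 >= 1 && j - 1 >= 1) {
        int jd = (i - 1) + dlo + c;
        if (jd >= 1 && jd <= n && H[prev + c] > 0) { hd = H[prev + c];
                                                     cont = true; }
      }
      int sdiag = hd + (is_match(q[i - 1], s[j - 1], is_nt) ? match
                                                            : mismatch);
      int h = 0; uint8_t ph = 0;
      if (sdiag > h) { h = sdiag; ph = cont ? 1 : 4; }
      if (e > h) { h = e; ph = 2; }
      if (f > h) { h = f; ph = 3; }
      H[row + c] = h; E[row + c] = e; F[row + c] = f;
      pH[row + c] = ph; pE[row + c] = pe; pF[row + c] = pf;
      if (h > best) { best = h; bi = i; bc = c; }
    }
  }
  Aln a; a.ok = false;
  a.score = best;
  if (best <= 0) return a;
  // traceback
  int i = bi, c = bc;
  int matches = 0, mismatches = 0, gapopens = 0, gapcols = 0;
  int qmin = 1 << 30, qmax = 0, smin = 1 << 30, smax = 0;
  while (true) {
    size_t row = (size_t)i * W;
    uint8_t p = pH[row + c];
    if (p == 0) break;
    if (p == 1 || p == 4) {
      int j = i + dlo + c;
      if (is_match(q[i - 1], s[j - 1], is_nt)) ++matches; else ++mismatches;
      qmin = std::min(qmin, i); qmax = std::max(qmax, i);
      smin = std::min(smin, j); smax = std::max(smax, j);
      if (p == 4) break;
      --i;
    } else if (p == 2) {
      ++gapopens;
      while (true) {
        int j = i + dlo + c;
        ++gapcols;
        smin = std::min(smin, j); smax = std::max(smax, j);
        uint8_t pe = pE[(size_t)i * W + c];
        --c;
        if (pe == 0) break;
      }
    } else {  // p == 3
      ++gapopens;
      while (true) {
        ++gapcols;
        qmin = std::min(qmin, i); qmax = std::max(qmax, i);
        uint8_t pf = pF[(size_t)i * W + c];
        --i; ++c;
        if (pf == 0) break;
      }
    }
  }
  a.matches = matches; a.mismatches = mismatches; a.gapopens = gapopens;
  a.columns = matches + mismatches + gapcols;
  a.qs = qmin; a.qe = qmax; a.ss = smin; a.se = smax;
  a.ok = matches > 0;
  return a;
}

struct RawHit {
  int qidx, sidx, score, matches, mismatches, gapopens, columns;
  int qs, qe, ss, se;
  int strand;  // +1 / -1
};

static void search_one(const KIndex& idx, const std::string& query,
                       int qidx, int strand, int qlen_fwd,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int band, std::vector<RawHit>& out,
                       std::vector<int>& H, std::vector<int>& E,
                       std::vector<int>& F, std::vector<uint8_t>& pH,
                       std::vector<uint8_t>& pE, std::vector<uint8_t>& pF) {
  int k = idx.k, m = (int)query.size();
  if (m < k) return;
  // seeds: (entry, diag)
  std::map<int, std::vector<int> > diags;  // ordered by entry for determinism
  uint64_t key = 0, mask = (1ULL << (5 * k)) - 1;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = chcode(query[i], idx.is_nt);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 5) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::unordered_map<uint64_t,
        std::vector<std::pair<int32_t,int32_t> > >::const_iterator it =
          idx.pos.find(key);
      if (it != idx.pos.end()) {
        int qpos = i - k + 1;
        for (size_t h = 0; h < it->second.size(); ++h)
          diags[it->second[h].first].push_back(it->second[h].second - qpos);
      }
    }
  }
  const int MAXSPAN = 160;  // cap on diagonal spread per extension window
  for (std::map<int, std::vector<int> >::iterator it = diags.begin();
       it != diags.end(); ++it) {
    int e = it->first;
    std::vector<int>& dv = it->second;
    std::sort(dv.begin(), dv.end());
    dv.erase(std::unique(dv.begin(), dv.end()), dv.end());
    const std::string& subj = idx.seqs[e];
    size_t g0 = 0;
    for (size_t g = 1; g <= dv.size(); ++g) {
      bool cut = (g == dv.size()) || (dv[g] - dv[g - 1] > band) ||
                 (dv[g] - dv[g0] > MAXSPAN);
      if (!cut) continue;
      int dmin = dv[g0], dmax = dv[g - 1];
      int dlo = dmin - band, dhi = dmax + band;
      Aln a = band_align(query, subj, dlo, dhi, match, mismatch, gap_open,
                         gap_extend, idx.is_nt, H, E, F, pH, pE, pF);
      if (a.ok) {
        RawHit rh;
        rh.qidx = qidx; rh.sidx = e; rh.score = a.score;
        rh.matches = a.matches; rh.mismatches = a.mismatches;
        rh.gapopens = a.gapopens; rh.columns = a.columns;
        rh.strand = strand;
        if (strand > 0) {
          rh.qs = a.qs; rh.qe = a.qe; rh.ss = a.ss; rh.se = a.se;
        } else {  // map to forward query; subject start > end marks minus
          rh.qs = qlen_fwd - a.qe + 1; rh.qe = qlen_fwd - a.qs + 1;
          rh.ss = a.se; rh.se = a.ss;
        }
        out.push_back(rh);
      }
      g0 = g;
    }
  }
}

// [[Rcpp::export]]
List cpp_search_batch(SEXP ptr, CharacterVector queries, int match,
                      int mismatch, int gap_open, int gap_extend, int band,
                      bool both_strands) {
  XPtr<KIndex> idx(ptr);
  std::vector<RawHit> hits;
  std::vector<int> H, E, F;
  std::vector<uint8_t> pH, pE, pF;
  int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    for (size_t i = 0; i < q.size(); ++i) q[i] = upc(q[i]);
    std::vector<RawHit> qh;
    search_one(*idx, q, qi, +1, (int)q.size(), match, mismatch, gap_open,
               gap_extend, band, qh, H, E, F, pH, pE, pF);
    if (both_strands && idx->is_nt) {
      std::string rc = revcomp(q);
      search_one(*idx, rc, qi, -1, (int)q.size(), match, mismatch, gap_open,
                 gap_extend, band, qh, H, E, F, pH, pE, pF);
    }
    // dedupe identical intervals, keep best score
    std::map<std::vector<int>, size_t> seen;
    for (size_t h = 0; h < qh.size(); ++h) {
      std::vector<int> keyv(6);
      keyv[0] = qh[h].sidx; keyv[1] = qh[h].strand;
      keyv[2] = qh[h].qs; keyv[3] = qh[h].qe;
      keyv[4] = qh[h].ss; keyv[5] = qh[h].se;
      std::map<std::vector<int>, size_t>::iterator f = seen.find(keyv);
      if (f == seen.end()) {
        seen[keyv] = hits.size();
        hits.push_back(qh[h]);
      } else if (qh[h].score > hits[f->second].score) {
        hits[f->second] = qh[h];
      }
    }
  }
  int n = (int)hits.size();
  IntegerVector qidx(n), sidx(n), score(n), matches(n), mism(n), gopen(n),
      cols(n), qs(n), qe(n), ss(n), se(n), strand(n);
  for (int i = 0; i < n; ++i) {
    qidx[i] = hits[i].qidx + 1; sidx[i] = hits[i].sidx + 1;
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    mism[i] = hits[i].mismatches; gopen[i] = hits[i].gapopens;
    cols[i] = hits[i].columns; qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se; strand[i] = hits[i].strand;
  }
  return List::create(_["qidx"] = qidx, _["sidx"] = sidx, _["score"] = score,
                      _["matches"] = matches, _["mismatches"] = mism,
                      _["gap_opens"] = gopen, _["columns"] = cols,
                      _["qstart"] = qs, _["qend"] = qe, _["sstart"] = ss,
                      _["send"] = se, _["strand"] = strand);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
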