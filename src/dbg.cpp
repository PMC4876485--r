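// Colored de Bruijn graph core: canonical k-mer counting, bidirected graph
// condensation into unitigs, and coverage-aware tip clipping.
//
// k-mers are 2-bit packed (A=0, C=1, G=2, T=3) into 64-bit words, so k <= 31
// (edge witnesses are (k+1)-mers, packed at up to 32 bases). Packing order is
// most-significant = first base, which makes numeric order on the packed value
// identical to lexicographic order on the string.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}
static const char BITS2BASE[5] = "ACGT";

static inline uint64_t rc_enc(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static std::string dec_enc(uint64_t v, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = BITS2BASE[v & 3ULL];
    v >>= 2;
  }
  return s;
}

static inline bool enc_str(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static const double COUNT_SATURATION = 4294967295.0;  // 2^32 - 1

// Count canonical k-mers of one read set and collect canonical (k+1)-mer edge
// witnesses. Maximal ACGT runs are used; any other byte breaks the run.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer between 3 and 31");
  const uint64_t maskK = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int k1 = k + 1;
  const uint64_t maskK1 = (k1 == 32) ? ~0ULL : ((1ULL << (2 * k1)) - 1ULL);

  std::unordered_map<uint64_t, uint64_t> counts;
  std::unordered_set<uint64_t> edges;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    if (seqs[r] == NA_STRING) continue;
    const char* s = CHAR(seqs[r]);
    uint64_t km = 0, em = 0;
    int run = 0;
    for (const char* p = s; *p; ++p) {
      int b = base2bits(*p);
      if (b < 0) { run = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & maskK;
      em = ((em << 2) | (uint64_t)b) & maskK1;
      ++run;
      if (run >= k) {
        uint64_t rc = rc_enc(km, k);
        ++counts[km < rc ? km : rc];
      }
      if (run >= k1) {
        uint64_t rc = rc_enc(em, k1);
        edges.insert(em < rc ? em : rc);
      }
    }
  }

  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers((R_xlen_t)keys.size());
  NumericVector cnt((R_xlen_t)keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[(R_xlen_t)i] = dec_enc(keys[i], k);
    double c = (double)counts[keys[i]];
    cnt[(R_xlen_t)i] = c > COUNT_SATURATION ? COUNT_SATURATION : c;
  }
  std::vector<uint64_t> ekeys(edges.begin(), edges.end());
  std::sort(ekeys.begin(), ekeys.end());
  CharacterVector ev((R_xlen_t)ekeys.size());
  for (size_t i = 0; i < ekeys.size(); ++i) ev[(R_xlen_t)i] = dec_enc(ekeys[i], k1);
  return List::create(_["kmers"] = kmers, _["counts"] = cnt, _["edges"] = ev);
}

// Canonical k-mer of every k-window of seq; NA where the window contains a
// non-ACGT byte.
// [[Rcpp::export]]
CharacterVector cpp_kmer_windows(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  R_xlen_t n = (R_xlen_t)seq.size();
  if (n < k) return CharacterVector(0);
  const uint64_t maskK = (1ULL << (2 * k)) - 1ULL;
  CharacterVector out(n - k + 1);
  uint64_t km = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(seq[(size_t)i]);
    if (b < 0) { run = 0; } else {
      km = ((km << 2) | (uint64_t)b) & maskK;
      ++run;
    }
    if (i >= k - 1) {
      if (run >= k) {
        uint64_t rc = rc_enc(km, k);
        out[i - k + 1] = dec_enc(km < rc ? km : rc, k);
      } else {
        out[i - k + 1] = NA_STRING;
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------
// Bidirected graph machinery. Oriented vertex id = (kept_index << 1) | strand,
// strand 0 = the canonical string as stored, strand 1 = its reverse
// complement. in-degree(v) == out-degree(flip(v)).

struct DBG {
  int k = 0;
  int n = 0;                          // kept nodes
  std::vector<int> orig;              // kept index -> original 0-based index
  std::vector<uint64_t> enc;          // canonical encodings of kept nodes
  std::vector<std::vector<int>> out;  // 2n oriented adjacency, sorted unique
};

static inline int ov_node(int ov) { return ov >> 1; }
static inline int ov_flip(int ov) { return ov ^ 1; }

static DBG build_dbg(const CharacterVector& kmers, const CharacterVector& edges,
                     int k, const LogicalVector& keep) {
  DBG g;
  g.k = k;
  std::unordered_map<uint64_t, int> id;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (!keep[i]) continue;
    uint64_t v;
    if (!enc_str(CHAR(kmers[i]), k, v)) stop("non-ACGT k-mer in table");
    int j = g.n++;
    g.orig.push_back((int)i);
    g.enc.push_back(v);
    id.emplace(v, j);
  }
  g.out.assign((size_t)(2 * g.n), {});
  const uint64_t maskK = (1ULL << (2 * k)) - 1ULL;
  for (R_xlen_t e = 0; e < edges.size(); ++e) {
    uint64_t w;
    if (!enc_str(CHAR(edges[e]), k + 1, w)) stop("non-ACGT edge witness");
    uint64_t passes[2] = {w, rc_enc(w, k + 1)};
    for (int t = 0; t < 2; ++t) {
      uint64_t p = passes[t] >> 2;
      uint64_t s = passes[t] & maskK;
      uint64_t pc = rc_enc(p, k), sc = rc_enc(s, k);
      int pstr = p <= pc ? 0 : 1;
      int sstr = s <= sc ? 0 : 1;
      uint64_t pk = pstr ? pc : p, sk = sstr ? sc : s;
      auto ip = id.find(pk), is = id.find(sk);
      if (ip == id.end() || is == id.end()) continue;
      g.out[(size_t)((ip->second << 1) | pstr)].push_back((is->second << 1) | sstr);
    }
  }
  for (auto& v : g.out) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  return g;
}

struct Unitigs {
  std::vector<std::vector<int>> paths;  // oriented kept ids
  std::vector<std::string> seqs;
};

static std::string path_seq(const DBG& g, const std::vector<int>& path) {
  uint64_t e0 = g.enc[(size_t)ov_node(path[0])];
  if (path[0] & 1) e0 = rc_enc(e0, g.k);
  std::string s = dec_enc(e0, g.k);
  for (size_t i = 1; i < path.size(); ++i) {
    uint64_t e = g.enc[(size_t)ov_node(path[i])];
    if (path[i] & 1) e = rc_enc(e, g.k);
    s.push_back(BITS2BASE[e & 3ULL]);
  }
  return s;
}

static std::string rc_string(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = BITS2BASE[3 - base2bits(c)];
  return r;
}

static Unitigs condense_dbg(const DBG& g) {
  Unitigs u;
  std::vector<char> visited((size_t)g.n, 0);
  for (int start = 0; start < g.n; ++start) {
    if (visited[(size_t)start]) continue;
    visited[(size_t)start] = 1;
    std::vector<int> path{start << 1};
    // forward
    int cur = start << 1;
    for (;;) {
      const auto& outs = g.out[(size_t)cur];
      if (outs.size() != 1) break;
      int nxt = outs[0];
      if (g.out[(size_t)ov_flip(nxt)].size() != 1) break;  // indeg(nxt) != 1
      if (visited[(size_t)ov_node(nxt)]) break;
      visited[(size_t)ov_node(nxt)] = 1;
      path.push_back(nxt);
      cur = nxt;
    }
    // backward: walk forward from the flip of the start
    cur = ov_flip(start << 1);
    std::vector<int> pre;
    for (;;) {
      const auto& outs = g.out[(size_t)cur];
      if (outs.size() != 1) break;
      int nxt = outs[0];
      if (g.out[(size_t)ov_flip(nxt)].size() != 1) break;
      if (visited[(size_t)ov_node(nxt)]) break;
      visited[(size_t)ov_node(nxt)] = 1;
      pre.push_back(ov_flip(nxt));
      cur = nxt;
    }
    if (!pre.empty()) {
      std::reverse(pre.begin(), pre.end());
      pre.insert(pre.end(), path.begin(), path.end());
      path.swap(pre);
    }
    std::string s = path_seq(g, path);
    std::string r = rc_string(s);
    if (r < s) {
      s.swap(r);
      std::reverse(path.begin(), path.end());
      for (auto& ov : path) ov = ov_flip(ov);
    }
    u.paths.push_back(std::move(path));
    u.seqs.push_back(std::move(s));
  }
  return u;
}

// Condense the kept subgraph into unitigs.
// Returns 1-based original node indices, strand flags, and sequences.
// [[Rcpp::export]]
List cpp_condense(CharacterVector kmers, CharacterVector edges, int k,
                  LogicalVector keep) {
  DBG g = build_dbg(kmers, edges, k, keep);
  Unitigs u = condense_dbg(g);
  R_xlen_t nu = (R_xlen_t)u.paths.size();
  List paths(nu), strands(nu);
  CharacterVector seqs(nu);
  for (R_xlen_t i = 0; i < nu; ++i) {
    const auto& p = u.paths[(size_t)i];
    IntegerVector idx((R_xlen_t)p.size()), str((R_xlen_t)p.size());
    for (size_t j = 0; j < p.size(); ++j) {
      idx[(R_xlen_t)j] = g.orig[(size_t)ov_node(p[j])] + 1;
      str[(R_xlen_t)j] = p[j] & 1;
    }
    paths[i] = idx;
    strands[i] = str;
    seqs[i] = u.seqs[(size_t)i];
  }
  return List::create(_["paths"] = paths, _["strands"] = strands,
                      _["seqs"] = seqs);
}

// Oriented adjacency as a flat table for debugging/inspection:
// from (canonical k-mer), from_strand, to, to_strand.
// [[Rcpp::export]]
DataFrame cpp_adjacency(CharacterVector kmers, CharacterVector edges, int k,
                        LogicalVector keep) {
  DBG g = build_dbg(kmers, edges, k, keep);
  std::vector<std::string> from, to;
  std::vector<int> fs, ts;
  for (int ov = 0; ov < 2 * g.n; ++ov) {
    for (int w : g.out[(size_t)ov]) {
      from.push_back(dec_enc(g.enc[(size_t)ov_node(ov)], k));
      fs.push_back(ov & 1);
      to.push_back(dec_enc(g.enc[(size_t)ov_node(w)], k));
      ts.push_back(w & 1);
    }
  }
  return DataFrame::create(_["from"] = from, _["from_strand"] = fs,
                           _["to"] = to, _["to_strand"] = ts,
                           _["stringsAsFactors"] = false);
}

// Iterative tip clipping. A unitig is a clippable tip when exactly one of its
// ends is a dead end, its sequence is shorter than max_tip_len, and the best
// alternative branch at its attachment junction has strictly greater
// max-over-colors average coverage. Repeats to fixpoint; returns updated keep.
// [[Rcpp::export]]
LogicalVector cpp_clip_tips(CharacterVector kmers, CharacterVector edges, int k,
                            LogicalVector keep, NumericMatrix counts,
                            double max_tip_len) {
  LogicalVector kp = clone(keep);
  int m = counts.ncol();
  for (;;) {
    DBG g = build_dbg(kmers, edges, k, kp);
    Unitigs u = condense_dbg(g);
    size_t nu = u.paths.size();
    std::vector<int> unitig_of((size_t)g.n, -1);
    std::vector<double> covmax(nu, 0.0);
    std::vector<double> ulen(nu, 0.0);
    for (size_t i = 0; i < nu; ++i) {
      const auto& p = u.paths[i];
      for (int ov : p) unitig_of[(size_t)ov_node(ov)] = (int)i;
      double best = 0.0;
      for (int c = 0; c < m; ++c) {
        double s = 0.0;
        for (int ov : p) s += counts(g.orig[(size_t)ov_node(ov)], c);
        double avg = s / (double)p.size();
        if (avg > best) best = avg;
      }
      covmax[i] = best;
      ulen[i] = (double)(k + (int)p.size() - 1);
    }
    bool removed = false;
    std::vector<char> drop(nu, 0);
    for (size_t i = 0; i < nu; ++i) {
      const auto& p = u.paths[i];
      int front = p.front(), back = p.back();
      bool dead_start = g.out[(size_t)ov_flip(front)].empty();
      bool dead_end = g.out[(size_t)back].empty();
      if (dead_start == dead_end) continue;  // isolated or internal: not a tip
      if (ulen[i] >= max_tip_len) continue;
      int uL = dead_start ? back : ov_flip(front);
      double best = -1.0;
      for (int j : g.out[(size_t)uL]) {
        for (int w : g.out[(size_t)ov_flip(j)]) {
          int sib = ov_flip(w);  // competing in-branch of junction j
          if (sib == uL) continue;
          int cu = unitig_of[(size_t)ov_node(sib)];
          if (cu < 0 || cu == (int)i) continue;
          if (covmax[(size_t)cu] > best) best = covmax[(size_t)cu];
        }
      }
      if (best > covmax[i]) { drop[i] = 1; removed = true; }
    }
    if (!removed) break;
    for (size_t i = 0; i < nu; ++i) {
      if (!drop[i]) continue;
      for (int ov : u.paths[i]) kp[g.orig[(size_t)ov_node(ov)]] = FALSE;
    }
  }
  return kp;
}
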