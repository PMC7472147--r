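// Hot loops of the pipeline: k-mer counting / unitig traversal for the de
// Bruijn assembler, seed-and-extend ungapped read subtraction, and seeded
// X-drop peptide extension for the translated homology search.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <deque>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline bool clean_window(const std::string& s, size_t pos, size_t k) {
  for (size_t i = pos; i < pos + k; ++i)
    if (!is_acgt(s[i])) return false;
  return true;
}

static inline std::string canon(const std::string& km) {
  std::string rc = revcomp(km);
  return km <= rc ? km : rc;
}

// ---------------------------------------------------------------------------
// de Bruijn graph: canonical k-mer counting and unitig traversal
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector reads, int k, int min_count) {
  std::unordered_map<std::string, int> cnt;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      if (!clean_window(s, p, k)) continue;
      cnt[canon(s.substr(p, k))]++;
    }
  }
  std::vector<std::string> keys;
  std::vector<int> vals;
  keys.reserve(cnt.size());
  for (auto& kv : cnt)
    if (kv.second >= min_count) { keys.push_back(kv.first); vals.push_back(kv.second); }
  return List::create(_["kmer"] = wrap(keys), _["count"] = wrap(vals));
}

struct DBG {
  std::unordered_map<std::string, int> cnt;  // canonical k-mer -> count
  int k;
  bool has(const std::string& km) const { return cnt.find(canon(km)) != cnt.end(); }
  int count(const std::string& km) const {
    auto it = cnt.find(canon(km));
    return it == cnt.end() ? 0 : it->second;
  }
  std::vector<std::string> succ(const std::string& km) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    for (char b : B) {
      std::string y = km.substr(1) + b;
      if (has(y)) out.push_back(y);
    }
    return out;
  }
  std::vector<std::string> pred(const std::string& km) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    for (char b : B) {
      std::string y = std::string(1, b) + km.substr(0, km.size() - 1);
      if (has(y)) out.push_back(y);
    }
    return out;
  }
};

struct Unitig {
  std::string seq;
  double cov;
  size_t n_kmers;
  bool cycle;
  std::string front_kmer, back_kmer;  // oriented terminal k-mers of the path
};

static std::vector<Unitig> traverse_unitigs(const DBG& g) {
  std::vector<Unitig> out;
  std::unordered_set<std::string> visited;  // canonical
  std::vector<std::string> keys;
  keys.reserve(g.cnt.size());
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());  // deterministic traversal order
  int k = g.k;
  for (auto& start : keys) {
    if (visited.count(start)) continue;
    std::deque<std::string> path;
    path.push_back(start);
    visited.insert(start);
    bool cycle = false;
    // extend forward
    std::string cur = start;
    while (true) {
      auto ss = g.succ(cur);
      if (ss.size() != 1) break;
      const std::string& nxt = ss[0];
      if (g.pred(nxt).size() != 1) break;
      if (nxt == start) { cycle = true; break; }  // perfect cycle
      std::string cn = canon(nxt);
      if (visited.count(cn)) break;
      path.push_back(nxt);
      visited.insert(cn);
      cur = nxt;
    }
    // extend backward (cycles are already closed)
    if (!cycle) {
      cur = start;
      while (true) {
        auto pp = g.pred(cur);
        if (pp.size() != 1) break;
        const std::string& prv = pp[0];
        if (g.succ(prv).size() != 1) break;
        std::string cn = canon(prv);
        if (visited.count(cn)) break;
        path.push_front(prv);
        visited.insert(cn);
        cur = prv;
      }
    }
    Unitig u;
    u.seq = path.front();
    for (size_t i = 1; i < path.size(); ++i) u.seq.push_back(path[i].back());
    if (cycle) u.seq += path.front().substr(0, k - 1);  // terminal redundancy wrap
    double c = 0;
    for (auto& p : path) c += g.count(p);
    u.cov = c / path.size();
    u.n_kmers = path.size();
    u.cycle = cycle;
    u.front_kmer = path.front();
    u.back_kmer = path.back();
    out.push_back(u);
  }
  return out;
}

// Unitigs from a (filtered) canonical k-mer table.  clip_tips removes, in one
// pass, short dead-end spurs hanging off a branching node (< 2k bases) and
// recomputes; genuine isolated fragments (dead ends on both sides) are kept.
// [[Rcpp::export]]
List unitigs_cpp(CharacterVector kmers, IntegerVector counts, int k, bool clip_tips) {
  DBG g;
  g.k = k;
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    g.cnt[as<std::string>(kmers[i])] = counts[i];
  std::vector<Unitig> us = traverse_unitigs(g);
  if (clip_tips) {
    bool removed = false;
    for (auto& u : us) {
      if ((int)u.seq.size() >= 2 * k || u.cycle) continue;
      auto preds = g.pred(u.front_kmer);
      auto succs = g.succ(u.back_kmer);
      // exclude path-internal neighbours for single-kmer unitigs
      bool dead_front = preds.empty();
      bool dead_back = succs.empty();
      if (dead_front == dead_back) continue;  // isolated or through-path: keep
      bool branch_attached = false;
      if (dead_front) {
        for (auto& y : succs) if (g.pred(y).size() >= 2) branch_attached = true;
      } else {
        for (auto& y : preds) if (g.succ(y).size() >= 2) branch_attached = true;
      }
      if (!branch_attached) continue;
      // drop this unitig's k-mers
      for (size_t p = 0; p + (size_t)k <= u.seq.size(); ++p)
        g.cnt.erase(canon(u.seq.substr(p, k)));
      removed = true;
    }
    if (removed) us = traverse_unitigs(g);
  }
  R_xlen_t n = us.size();
  CharacterVector seqs(n);
  NumericVector cov(n);
  IntegerVector nk(n);
  LogicalVector cyc(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    seqs[i] = us[i].seq;
    cov[i] = us[i].cov;
    nk[i] = (int)us[i].n_kmers;
    cyc[i] = us[i].cycle;
  }
  return List::create(_["seq"] = seqs, _["kmer_coverage"] = cov,
                      _["n_kmers"] = nk, _["cycle"] = cyc);
}

// ---------------------------------------------------------------------------
// Background subtraction: exact seed, ungapped diagonal scan for a window of
// >= min_len read bases with <= max_mm mismatches (no gaps, either strand).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List subtract_flags_cpp(CharacterVector reads, CharacterVector refs,
                        int seed_len, int min_len, int max_mm) {
  // index all seed_len-mers of the forward reference strands
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  std::vector<std::string> rf(refs.size());
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    rf[r] = as<std::string>(refs[r]);
    const std::string& s = rf[r];
    if ((int)s.size() < seed_len) continue;
    for (size_t p = 0; p + (size_t)seed_len <= s.size(); ++p) {
      if (!clean_window(s, p, seed_len)) continue;
      idx[s.substr(p, seed_len)].push_back({(int)r, (int)p});
    }
  }
  R_xlen_t n = reads.size();
  LogicalVector flag(n);
  IntegerVector hit_ref(n, NA_INTEGER), hit_pos(n, NA_INTEGER);
  CharacterVector hit_strand(n, NA_STRING);

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = fwd.size();
    flag[i] = false;
    if (L < min_len) continue;
    bool found = false;
    for (int ori = 0; ori < 2 && !found; ++ori) {
      const std::string q = ori == 0 ? fwd : revcomp(fwd);
      std::unordered_set<long long> tried;  // (ref, diagonal) pairs
      for (int p = 0; p + seed_len <= L && !found; ++p) {
        if (!clean_window(q, p, seed_len)) continue;
        auto it = idx.find(q.substr(p, seed_len));
        if (it == idx.end()) continue;
        for (auto& hp : it->second) {
          int r = hp.first;
          long long diag = (long long)hp.second - p;
          long long key = ((long long)r << 34) ^ (diag + (1LL << 32));
          if (tried.count(key)) continue;
          tried.insert(key);
          const std::string& R = rf[r];
          int RL = R.size();
          int i0 = std::max(0LL, -diag);                 // first read index on diagonal
          int i1 = std::min((long long)L, (long long)RL - diag);  // one past last
          if (i1 - i0 < min_len) continue;
          // sliding window of min_len with mismatch count
          int mm = 0, lo = i0;
          bool ok = false;
          for (int hi = i0; hi < i1; ++hi) {
            char a = q[hi], b = R[hi + diag];
            if (a != b || !is_acgt(a)) ++mm;  // N counts as mismatch
            if (hi - lo + 1 > min_len) {
              char a2 = q[lo], b2 = R[lo + diag];
              if (a2 != b2 || !is_acgt(a2)) --mm;
              ++lo;
            }
            if (hi - lo + 1 >= min_len && mm <= max_mm) { ok = true; break; }
          }
          if (ok) {
            flag[i] = true;
            hit_ref[i] = r + 1;
            hit_pos[i] = (int)(lo + diag) + 1;
            hit_strand[i] = ori == 0 ? "+" : "-";
            found = true;
            break;
          }
        }
      }
    }
  }
  return List::create(_["background"] = flag, _["ref"] = hit_ref,
                      _["ref_start"] = hit_pos, _["strand"] = hit_strand);
}

// ---------------------------------------------------------------------------
// Translated search: exact word seeding over peptides, ungapped X-drop
// extension.  Stop codons ('*') terminate extension; scores come from a
// 128x128 char-indexed matrix prepared in R from BLOSUM62.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame seed_extend_cpp(CharacterVector qpeps, CharacterVector dbpeps,
                          IntegerMatrix smat, int word, int xdrop) {
  // index db words
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> widx;
  std::vector<std::string> db(dbpeps.size());
  for (R_xlen_t s = 0; s < dbpeps.size(); ++s) {
    db[s] = as<std::string>(dbpeps[s]);
    const std::string& ps = db[s];
    if ((int)ps.size() < word) continue;
    for (size_t p = 0; p + (size_t)word <= ps.size(); ++p) {
      std::string w = ps.substr(p, word);
      if (w.find('*') != std::string::npos) continue;
      widx[w].push_back({(int)s, (int)p});
    }
  }
  std::vector<int> o_q, o_s, o_qs, o_qe, o_ss, o_se, o_sc;
  for (R_xlen_t qi = 0; qi < qpeps.size(); ++qi) {
    std::string q = as<std::string>(qpeps[qi]);
    int ql = q.size();
    if (ql < word) continue;
    // covered query intervals per (subject, diagonal)
    std::unordered_map<long long, std::vector<std::pair<int, int>>> covered;
    for (int p = 0; p + word <= ql; ++p) {
      std::string w = q.substr(p, word);
      if (w.find('*') != std::string::npos) continue;
      auto it = widx.find(w);
      if (it == widx.end()) continue;
      for (auto& hp : it->second) {
        int si = hp.first, sp = hp.second;
        const std::string& sub = db[si];
        int sl = sub.size();
        long long d = (long long)sp - p;
        long long key = ((long long)si << 34) ^ (d + (1LL << 32));
        bool skip = false;
        auto cit = covered.find(key);
        if (cit != covered.end())
          for (auto& iv : cit->second)
            if (p >= iv.first && p <= iv.second) { skip = true; break; }
        if (skip) continue;
        // seed score
        int sc = 0;
        for (int t = 0; t < word; ++t)
          sc += smat((unsigned char)q[p + t], (unsigned char)sub[sp + t]);
        // extend right
        int best = sc, qe = p + word - 1, run = sc;
        for (int i = p + word; i < ql && i + d < sl; ++i) {
          char a = q[i], b = sub[i + d];
          if (a == '*' || b == '*') break;
          run += smat((unsigned char)a, (unsigned char)b);
          if (run > best) { best = run; qe = i; }
          else if (best - run > xdrop) break;
        }
        // extend left
        int bestl = 0, runl = 0, qs = p;
        for (int i = p - 1; i >= 0 && i + d >= 0; --i) {
          char a = q[i], b = sub[i + d];
          if (a == '*' || b == '*') break;
          runl += smat((unsigned char)a, (unsigned char)b);
          if (runl > bestl) { bestl = runl; qs = i; }
          else if (bestl - runl > xdrop) break;
        }
        int total = best + bestl;
        covered[key].push_back({qs, qe});
        o_q.push_back((int)qi + 1);
        o_s.push_back(si + 1);
        o_qs.push_back(qs);
        o_qe.push_back(qe);
        o_ss.push_back((int)(qs + d));
        o_se.push_back((int)(qe + d));
        o_sc.push_back(total);
      }
    }
  }
  return DataFrame::create(
      _["qidx"] = wrap(o_q), _["sidx"] = wrap(o_s),
      _["qs"] = wrap(o_qs), _["qe"] = wrap(o_qe),
      _["ss"] = wrap(o_ss), _["se"] = wrap(o_se),
      _["score"] = wrap(o_sc));
}
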