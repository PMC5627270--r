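// Low-level sequence kernels: end-to-end Hamming read mapper, canonical
// k-mer de Bruijn unitig assembler, gapless seed-and-extend local aligner,
// affine-gap Smith-Waterman for protein search, and suffix/prefix overlap
// detection. All loops are deterministic: hash maps are only used for
// lookups; any iteration that influences output order runs over sorted keys.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <cctype>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and friends: mismatch against everything
  }
}

static inline char code_base(int c) { return "ACGT"[c]; }

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[s.size() - 1 - i]);
    r[i] = (c < 4) ? code_base(3 - c) : 'N';
  }
  return r;
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t rc_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (v & 3));
    v >>= 2;
  }
  return r;
}

// -------------------------------------------------------------------------
// Read mapper: end-to-end, substitutions only, best hit per read.
// Tie-break: fewest mismatches, then lowest target index, then leftmost
// position, then forward strand. Targets must be supplied pre-sorted by id.
// -------------------------------------------------------------------------

struct Hit {
  int mm, tgt, pos, strand; // strand 0 = '+', 1 = '-'
  bool operator<(const Hit& o) const {
    if (mm != o.mm) return mm < o.mm;
    if (tgt != o.tgt) return tgt < o.tgt;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
};

static inline int hamming_leq(const std::string& a, size_t apos,
                              const std::string& b, int limit) {
  int mm = 0;
  for (size_t i = 0; i < b.size(); ++i) {
    char x = a[apos + i], y = b[i];
    int cx = base_code(x), cy = base_code(y);
    if (cx != cy || cx == 4) {
      if (++mm > limit) return limit + 1;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector targets,
                        int max_mm) {
  const int K = 13;
  int nt = targets.size(), nr = reads.size();
  std::vector<std::string> tg(nt);
  for (int i = 0; i < nt; ++i) tg[i] = as<std::string>(targets[i]);

  // k-mer index over forward target strands
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  uint64_t mask = (K < 32) ? ((1ULL << (2 * K)) - 1) : ~0ULL;
  for (int t = 0; t < nt; ++t) {
    const std::string& s = tg[t];
    if ((int)s.size() < K) continue;
    uint64_t v = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c == 4) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= K) idx[v].push_back({t, (int)i - K + 1});
    }
  }

  std::vector<int> o_read, o_tgt, o_start, o_mm;
  std::vector<std::string> o_strand;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int L = (int)fwd.size();
    if (L == 0) continue;
    Hit best{max_mm + 1, -1, -1, 0};
    std::string rev = revcomp(fwd);
    int blocks = max_mm + 1;
    bool use_index = (L >= blocks * K);

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      if (use_index) {
        std::unordered_set<uint64_t> seen;
        int blen = L / blocks;
        for (int b = 0; b < blocks; ++b) {
          int off = b * blen;
          // encode K-mer at off
          uint64_t v = 0; bool ok = true;
          for (int i = 0; i < K; ++i) {
            int c = base_code(q[off + i]);
            if (c == 4) { ok = false; break; }
            v = (v << 2) | (uint64_t)c;
          }
          if (!ok) continue;
          auto it = idx.find(v);
          if (it == idx.end()) continue;
          for (auto& tp : it->second) {
            int t = tp.first, s = tp.second - off;
            if (s < 0 || s + L > (int)tg[t].size()) continue;
            uint64_t key = ((uint64_t)t << 32) | (uint32_t)s;
            if (!seen.insert(key).second) continue;
            int mm = hamming_leq(tg[t], s, q, max_mm);
            if (mm <= max_mm) {
              Hit h{mm, t, s, strand};
              if (h < best) best = h;
            }
          }
        }
      } else {
        for (int t = 0; t < nt; ++t) {
          int Lt = (int)tg[t].size();
          for (int s = 0; s + L <= Lt; ++s) {
            int mm = hamming_leq(tg[t], s, q, max_mm);
            if (mm <= max_mm) {
              Hit h{mm, t, s, strand};
              if (h < best) best = h;
            }
          }
        }
      }
    }
    if (best.tgt >= 0) {
      o_read.push_back(r + 1);
      o_tgt.push_back(best.tgt + 1);
      o_start.push_back(best.pos);
      o_mm.push_back(best.mm);
      o_strand.push_back(best.strand == 0 ? "+" : "-");
    }
  }

  return DataFrame::create(_["read"] = o_read, _["target"] = o_tgt,
                           _["start"] = o_start, _["mismatches"] = o_mm,
                           _["strand"] = o_strand,
                           _["stringsAsFactors"] = false);
}

// -------------------------------------------------------------------------
// Canonical k-mer counting + unitig assembly
// -------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static void count_kmers(const std::vector<std::string>& reads, int k,
                        KmerMap& counts) {
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (const auto& s : reads) {
    if ((int)s.size() < k) continue;
    uint64_t v = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c == 4) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        uint64_t rc = rc_kmer(v, k);
        counts[std::min(v, rc)]++;
      }
    }
  }
}

struct Oriented { uint64_t node; bool fwd; };

static inline uint64_t canon(uint64_t v, int k) {
  uint64_t rc = rc_kmer(v, k);
  return std::min(v, rc);
}

static void successors(const Oriented& x, const KmerMap& kept, int k,
                       std::vector<Oriented>& out) {
  out.clear();
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t oval = x.fwd ? x.node : rc_kmer(x.node, k);
  for (uint64_t b = 0; b < 4; ++b) {
    uint64_t nxt = ((oval << 2) | b) & mask;
    uint64_t c = canon(nxt, k);
    if (kept.count(c)) out.push_back({c, nxt == c});
  }
}

static std::string kmer_string(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = code_base(v & 3); v >>= 2; }
  return s;
}

static std::string oriented_string(const Oriented& x, int k) {
  return kmer_string(x.fwd ? x.node : rc_kmer(x.node, k), k);
}

// iterative removal of k-mers much weaker than their graph neighbours
static void cleanup_weak(KmerMap& kept, int k, double ratio, int max_rounds) {
  if (ratio <= 0) return;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int round = 0; round < max_rounds; ++round) {
    std::vector<uint64_t> drop;
    for (auto& kv : kept) {
      uint64_t v = kv.first;
      uint32_t cnt = kv.second, maxn = 0;
      for (uint64_t b = 0; b < 4; ++b) {
        uint64_t s1 = ((v << 2) | b) & mask;            // forward successor
        uint64_t s2 = (v >> 2) | (b << (2 * (k - 1)));  // forward predecessor
        for (uint64_t cand : {canon(s1, k), canon(s2, k)}) {
          if (cand == v) continue;
          auto it = kept.find(cand);
          if (it != kept.end() && it->second > maxn) maxn = it->second;
        }
      }
      if (maxn > 0 && (double)cnt < ratio * (double)maxn) drop.push_back(v);
    }
    if (drop.empty()) break;
    for (uint64_t v : drop) kept.erase(v);
  }
}

static std::vector<std::string> build_unitigs(const KmerMap& kept, int k) {
  std::vector<uint64_t> keys;
  keys.reserve(kept.size());
  for (auto& kv : kept) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<uint64_t> visited;
  std::vector<std::string> contigs;
  std::vector<Oriented> ss, pp, tmp;

  auto walk = [&](Oriented x) {
    std::string seq = oriented_string(x, k);
    visited.insert(x.node);
    Oriented cur = x;
    while (true) {
      successors(cur, kept, k, ss);
      if (ss.size() != 1) break;
      Oriented nxt = ss[0];
      successors({nxt.node, !nxt.fwd}, kept, k, tmp); // preds of nxt
      if (tmp.size() != 1) break;
      if (visited.count(nxt.node)) break;
      visited.insert(nxt.node);
      std::string os = oriented_string(nxt, k);
      seq.push_back(os[k - 1]);
      cur = nxt;
    }
    contigs.push_back(seq);
  };

  for (uint64_t key : keys) {
    if (visited.count(key)) continue;
    for (int f = 1; f >= 0; --f) {
      Oriented x{key, f == 1};
      // predecessors of x are reversals of successors of rev(x)
      successors({key, !x.fwd}, kept, k, pp);
      bool start = false;
      if (pp.size() != 1) {
        start = true;
      } else {
        Oriented p{pp[0].node, !pp[0].fwd};
        successors(p, kept, k, ss);
        if (ss.size() != 1) start = true;
      }
      if (start && !visited.count(key)) walk(x);
    }
  }
  // remaining nodes sit on perfect cycles
  for (uint64_t key : keys) {
    if (!visited.count(key)) walk({key, true});
  }
  return contigs;
}

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector reads, int k, int min_count,
                             double cleanup_ratio, int min_contig_len) {
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);
  KmerMap counts;
  count_kmers(rd, k, counts);
  KmerMap kept;
  for (auto& kv : counts)
    if ((int)kv.second >= min_count) kept.insert(kv);
  counts.clear();
  cleanup_weak(kept, k, cleanup_ratio, 4 * k);
  std::vector<std::string> contigs = build_unitigs(kept, k);
  std::vector<std::string> out;
  for (auto& c : contigs)
    if ((int)c.size() >= min_contig_len) out.push_back(c);
  return wrap(out);
}

// Repeat library: unitigs over k-mers whose count exceeds a multiple of the
// median k-mer count (simplified high-abundance-k-mer repeat detection).
// [[Rcpp::export]]
CharacterVector cpp_repeat_contigs(CharacterVector reads, int k,
                                   double mult) {
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);
  KmerMap counts;
  count_kmers(rd, k, counts);
  if (counts.empty()) return CharacterVector(0);
  std::vector<uint32_t> vals;
  vals.reserve(counts.size());
  for (auto& kv : counts) vals.push_back(kv.second);
  size_t mid = vals.size() / 2;
  std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
  double med = vals[mid];
  double thr = mult * med;
  KmerMap kept;
  for (auto& kv : counts)
    if ((double)kv.second >= thr) kept.insert(kv);
  std::vector<std::string> contigs = build_unitigs(kept, k);
  std::vector<std::string> out;
  for (auto& c : contigs)
    if ((int)c.size() >= 2 * k) out.push_back(c);
  return wrap(out);
}

// [[Rcpp::export]]
double cpp_median_kmer_count(CharacterVector reads, int k) {
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);
  KmerMap counts;
  count_kmers(rd, k, counts);
  if (counts.empty()) return NA_REAL;
  std::vector<uint32_t> vals;
  for (auto& kv : counts) vals.push_back(kv.second);
  size_t mid = vals.size() / 2;
  std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
  return (double)vals[mid];
}

// -------------------------------------------------------------------------
// Gapless local alignment (seed + diagonal Kadane), both strands.
// Score = matches - mismatches. Returns the best segment per query.
// -------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_best_local_hit(CharacterVector queries, CharacterVector targets,
                             int seed_k, int stride) {
  int nq = queries.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  for (int i = 0; i < nt; ++i) tg[i] = as<std::string>(targets[i]);

  uint64_t mask = (1ULL << (2 * seed_k)) - 1;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  for (int t = 0; t < nt; ++t) {
    const std::string& s = tg[t];
    if ((int)s.size() < seed_k) continue;
    uint64_t v = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c == 4) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= seed_k) idx[v].push_back({t, (int)i - seed_k + 1});
    }
  }

  IntegerVector r_tgt(nq, NA_INTEGER), r_score(nq, NA_INTEGER),
      r_qs(nq, NA_INTEGER), r_qe(nq, NA_INTEGER), r_ts(nq, NA_INTEGER),
      r_te(nq, NA_INTEGER), r_match(nq, NA_INTEGER), r_len(nq, NA_INTEGER);
  CharacterVector r_strand(nq, NA_STRING);

  for (int qi = 0; qi < nq; ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    int Lq = (int)fwd.size();
    if (Lq < seed_k) continue;
    std::string rev = revcomp(fwd);

    int best_score = 0, best_t = -1, best_qs = 0, best_qe = 0, best_ts = 0,
        best_match = 0, best_strand = 0;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      std::unordered_set<uint64_t> seen; // (t, diag) pairs
      for (int off = 0; off <= Lq - seed_k;
           off = (off + stride <= Lq - seed_k || off == Lq - seed_k)
                     ? off + stride
                     : Lq - seed_k) {
        uint64_t v = 0; bool ok = true;
        for (int i = 0; i < seed_k; ++i) {
          int c = base_code(q[off + i]);
          if (c == 4) { ok = false; break; }
          v = (v << 2) | (uint64_t)c;
        }
        if (ok) {
          auto it = idx.find(v);
          if (it != idx.end()) {
            for (auto& tp : it->second) {
              int t = tp.first;
              int diag = tp.second - off; // tpos - qpos
              uint64_t key =
                  ((uint64_t)t << 33) | (uint64_t)(uint32_t)(diag + (1 << 30));
              if (!seen.insert(key).second) continue;
              // Kadane along this diagonal
              const std::string& T = tg[t];
              int qlo = std::max(0, -diag);
              int qhi = std::min(Lq, (int)T.size() - diag);
              int cur = 0, curm = 0, curstart = qlo;
              for (int i = qlo; i < qhi; ++i) {
                int cq = base_code(q[i]), ct = base_code(T[i + diag]);
                bool m = (cq == ct && cq != 4);
                int vstep = m ? 1 : -1;
                if (cur <= 0) { cur = vstep; curm = m ? 1 : 0; curstart = i; }
                else { cur += vstep; curm += m ? 1 : 0; }
                bool better =
                    cur > best_score ||
                    (cur == best_score && best_t >= 0 &&
                     (t < best_t || (t == best_t && strand < best_strand)));
                if (better) {
                  best_score = cur; best_t = t; best_qs = curstart;
                  best_qe = i + 1; best_ts = curstart + diag;
                  best_match = curm; best_strand = strand;
                }
              }
            }
          }
        }
        if (off == Lq - seed_k) break;
      }
    }

    if (best_t >= 0 && best_score > 0) {
      r_tgt[qi] = best_t + 1;
      r_score[qi] = best_score;
      r_qs[qi] = best_qs;
      r_qe[qi] = best_qe;
      r_ts[qi] = best_ts;
      r_te[qi] = best_ts + (best_qe - best_qs);
      r_match[qi] = best_match;
      r_len[qi] = best_qe - best_qs;
      r_strand[qi] = best_strand == 0 ? "+" : "-";
    }
  }

  return DataFrame::create(
      _["target"] = r_tgt, _["score"] = r_score, _["qstart"] = r_qs,
      _["qend"] = r_qe, _["tstart"] = r_ts, _["tend"] = r_te,
      _["matches"] = r_match, _["aln_len"] = r_len, _["strand"] = r_strand,
      _["stringsAsFactors"] = false);
}

// -------------------------------------------------------------------------
// Smith-Waterman (affine gaps, BLOSUM62) for translated paralog search
// -------------------------------------------------------------------------

static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";

static const int BLOSUM62[24][24] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static inline int aa_index(char c) {
  const char* p = strchr(AA_ORDER, toupper(c));
  return p ? (int)(p - AA_ORDER) : 22; // unknown -> X
}

// score-only affine SW
// [[Rcpp::export]]
int cpp_sw_score(std::string q, std::string t, int gap_open, int gap_ext) {
  int m = (int)q.size(), n = (int)t.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> qi(m), ti(n);
  for (int i = 0; i < m; ++i) qi[i] = aa_index(q[i]);
  for (int j = 0; j < n; ++j) ti[j] = aa_index(t[j]);
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = 0, F = 0; // H[i-1][0] = 0
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - gap_open - gap_ext, E[j] - gap_ext);
      F = std::max(H[j - 1] - gap_open - gap_ext, F - gap_ext);
      int h = std::max(0, diag + BLOSUM62[qi[i - 1]][ti[j - 1]]);
      h = std::max(h, std::max(E[j], F));
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// full SW with traceback; returns alignment details
// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string t, int gap_open, int gap_ext) {
  int m = (int)q.size(), n = (int)t.size();
  std::vector<int> qi(m), ti(n);
  for (int i = 0; i < m; ++i) qi[i] = aa_index(q[i]);
  for (int j = 0; j < n; ++j) ti[j] = aa_index(t[j]);

  // 0 = stop, 1 = diag, 2 = up (gap in target), 3 = left (gap in query)
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), 0),
      F((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[at(i, j)] = std::max(H[at(i, j - 1)] - gap_open - gap_ext,
                             E[at(i, j - 1)] - gap_ext);
      F[at(i, j)] = std::max(H[at(i - 1, j)] - gap_open - gap_ext,
                             F[at(i - 1, j)] - gap_ext);
      int d = H[at(i - 1, j - 1)] + BLOSUM62[qi[i - 1]][ti[j - 1]];
      int h = 0; unsigned char dir = 0;
      if (d > h) { h = d; dir = 1; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; dir = 2; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; dir = 3; }
      H[at(i, j)] = h;
      tb[at(i, j)] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, ta;
  int i = bi, j = bj, n_ident = 0;
  while (i > 0 && j > 0 && H[at(i, j)] > 0) {
    unsigned char dir = tb[at(i, j)];
    if (dir == 0) break;
    if (dir == 1) {
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      if (toupper(q[i - 1]) == toupper(t[j - 1])) n_ident++;
      --i; --j;
    } else if (dir == 2) {
      qa.push_back(q[i - 1]); ta.push_back('-'); --i;
    } else {
      qa.push_back('-'); ta.push_back(t[j - 1]); --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["tstart"] = j, _["tend"] = bj,
                      _["n_ident"] = n_ident,
                      _["aln_len"] = (int)qa.size(), _["qaln"] = qa,
                      _["taln"] = ta);
}

// -------------------------------------------------------------------------
// Longest qualifying suffix(a)/prefix(b) overlap
// -------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_ov,
                      double min_id) {
  int la = (int)a.size(), lb = (int)b.size();
  int maxov = std::min(la, lb);
  for (int ov = maxov; ov >= min_ov; --ov) {
    int allow = (int)std::floor((1.0 - min_id) * ov);
    int mm = 0; bool ok = true;
    for (int i = 0; i < ov; ++i) {
      char x = a[la - ov + i], y = b[i];
      int cx = base_code(x), cy = base_code(y);
      if (cx != cy || cx == 4) {
        if (++mm > allow) { ok = false; break; }
      }
    }
    if (ok) return List::create(_["overlap"] = ov, _["mismatches"] = mm);
  }
  return List::create(_["overlap"] = 0, _["mismatches"] = NA_INTEGER);
}
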