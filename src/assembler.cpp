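// Greedy suffix-prefix assembler for error-free short reads.
// Repeatedly merges the pair of active sequences with the longest exact
// suffix-prefix overlap >= min_overlap, considering both orientations;
// ties pick the lexicographically smallest merged sequence, so the result
// does not depend on input order. Sequences are kept in canonical
// orientation (lexicographic min of sequence and reverse complement).
#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <set>
#include <unordered_set>
#include <map>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static std::string rc(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

static inline int code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

struct Unit {
  std::string seq[2];  // [0] canonical, [1] reverse complement
  long nreads = 0;
  bool alive = true;
};

struct Cand {
  int v;               // overlap length
  std::string merged;  // canonical merged sequence
  int ida, idb;        // left and right unit ids
};

struct CandCmp {
  const std::vector<Unit> *units;
  // priority_queue keeps the "largest"; we want: v desc, merged asc,
  // then smaller constituent pair, then ids (stability only)
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.v != b.v) return a.v < b.v;
    if (a.merged != b.merged) return a.merged > b.merged;
    const std::string &a1 = std::min((*units)[a.ida].seq[0], (*units)[a.idb].seq[0]);
    const std::string &a2 = std::max((*units)[a.ida].seq[0], (*units)[a.idb].seq[0]);
    const std::string &b1 = std::min((*units)[b.ida].seq[0], (*units)[b.idb].seq[0]);
    const std::string &b2 = std::max((*units)[b.ida].seq[0], (*units)[b.idb].seq[0]);
    if (a1 != b1) return a1 > b1;
    if (a2 != b2) return a2 > b2;
    if (a.ida != b.ida) return a.ida > b.ida;
    return a.idb > b.idb;
  }
};

typedef std::pair<int,int> UO;          // (unit, orientation)
struct PosEntry { int unit, orient, pos; };

class Assembler {
public:
  int K, min_ov;
  std::vector<Unit> units;
  std::unordered_map<uint64_t, std::vector<UO>> prefix_idx;
  std::unordered_map<uint64_t, std::vector<PosEntry>> pos_idx;
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;

  Assembler(int min_overlap)
    : K(std::min(min_overlap, 21)), min_ov(min_overlap),
      pq(CandCmp{&units}) {}

  bool kmer_at(const std::string &s, int p, uint64_t &key) const {
    key = 0;
    for (int t = 0; t < K; ++t) {
      int c = code(s[p + t]);
      if (c < 0) return false;
      key = (key << 2) | (uint64_t)c;
    }
    return true;
  }

  // rolling keys for every K-mer start; valid[p] == 0 where the window
  // contains a non-ACGT character
  void kmer_keys(const std::string &s, std::vector<uint64_t> &keys,
                 std::vector<char> &valid) const {
    int n = (int)s.size() - K + 1;
    keys.assign(std::max(n, 0), 0);
    valid.assign(std::max(n, 0), 0);
    if (n <= 0) return;
    uint64_t mask = (K >= 32) ? ~0ULL : ((1ULL << (2 * K)) - 1);
    uint64_t key = 0; int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int c = code(s[j]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= K) { keys[j - K + 1] = key; valid[j - K + 1] = 1; }
    }
  }

  void index_unit(int id) {
    std::vector<uint64_t> keys; std::vector<char> valid;
    for (int o = 0; o < 2; ++o) {
      const std::string &s = units[id].seq[o];
      if ((int)s.size() < K) continue;
      kmer_keys(s, keys, valid);
      if (valid[0]) prefix_idx[keys[0]].push_back({id, o});
      for (int p = 0; p < (int)keys.size(); ++p)
        if (valid[p]) pos_idx[keys[p]].push_back({id, o, p});
    }
  }

  int add_unit(const std::string &raw, long nreads) {
    Unit u;
    std::string r = rc(raw);
    u.seq[0] = std::min(raw, r);
    u.seq[1] = std::max(raw, r);
    if (u.seq[0] == u.seq[1]) u.seq[1] = u.seq[0];  // palindrome
    u.nreads = nreads;
    units.push_back(u);
    int id = (int)units.size() - 1;
    index_unit(id);
    return id;
  }

  void push_cand(int ida, int oa, int idb, int ob, int v) {
    const std::string &L = units[ida].seq[oa];
    const std::string &R = units[idb].seq[ob];
    std::string merged = L + R.substr(v);
    std::string mr = rc(merged);
    if (mr < merged) merged.swap(mr);
    pq.push(Cand{v, merged, ida, idb});
  }

  // enumerate candidates where `id` is the LEFT partner
  void cands_as_left(int id) {
    std::vector<uint64_t> keys; std::vector<char> valid;
    for (int oa = 0; oa < 2; ++oa) {
      const std::string &L = units[id].seq[oa];
      int len = (int)L.size();
      if (len < K) continue;
      kmer_keys(L, keys, valid);
      std::unordered_set<uint64_t> seen;  // (unit, orient) -> max v kept
      for (int p = 0; p + K <= len; ++p) {
        int v = len - p;
        if (v < min_ov) break;  // p ascending => v descending
        if (!valid[p]) continue;
        uint64_t key = keys[p];
        auto it = prefix_idx.find(key);
        if (it == prefix_idx.end()) continue;
        for (const UO &uo : it->second) {
          int idb = uo.first, ob = uo.second;
          if (idb == id || !units[idb].alive) continue;
          if (seen.count(((uint64_t)idb << 1) | ob)) continue;
          const std::string &R = units[idb].seq[ob];
          if (v > (int)R.size()) continue;
          if (std::memcmp(L.data() + p, R.data(), v) != 0) continue;
          seen.insert(((uint64_t)idb << 1) | ob);
          push_cand(id, oa, idb, ob, v);
        }
      }
      if (units[id].seq[0] == units[id].seq[1]) break;  // palindrome: one orientation
    }
  }

  // enumerate candidates where `id` is the RIGHT partner
  void cands_as_right(int id) {
    for (int ob = 0; ob < 2; ++ob) {
      const std::string &R = units[id].seq[ob];
      if ((int)R.size() < K) continue;
      uint64_t key;
      if (!kmer_at(R, 0, key)) continue;
      auto it = pos_idx.find(key);
      if (it == pos_idx.end()) continue;
      std::map<std::pair<int,int>, int> best_v;
      for (const PosEntry &pe : it->second) {
        if (pe.unit == id || !units[pe.unit].alive) continue;
        const std::string &L = units[pe.unit].seq[pe.orient];
        int v = (int)L.size() - pe.pos;
        if (v < min_ov || v > (int)R.size()) continue;
        if (std::memcmp(L.data() + pe.pos, R.data(), v) != 0) continue;
        auto kb = std::make_pair(pe.unit, pe.orient);
        auto bv = best_v.find(kb);
        if (bv == best_v.end() || v > bv->second) best_v[kb] = v;
      }
      for (auto &kv : best_v)
        push_cand(kv.first.first, kv.first.second, id, ob, kv.second);
      if (units[id].seq[0] == units[id].seq[1]) break;
    }
  }

  void run() {
    for (int id = 0; id < (int)units.size(); ++id) cands_as_left(id);
    while (!pq.empty()) {
      Cand c = pq.top(); pq.pop();
      if (!units[c.ida].alive || !units[c.idb].alive) continue;
      long nr = units[c.ida].nreads + units[c.idb].nreads;
      units[c.ida].alive = false;
      units[c.idb].alive = false;
      int id = add_unit(c.merged, nr);
      cands_as_left(id);
      cands_as_right(id);
    }
  }
};

// [[Rcpp::export(name = ".greedy_assemble_cpp")]]
List greedy_assemble_cpp(CharacterVector reads, int min_overlap, int min_contig_len) {
  Assembler asmb(min_overlap);
  for (int i = 0; i < reads.size(); ++i)
    asmb.add_unit(as<std::string>(reads[i]), 1);
  asmb.run();
  // collect: contigs (len >= min_contig_len) sorted by length desc, seq asc
  std::vector<int> keep;
  long unplaced = 0;
  for (int id = 0; id < (int)asmb.units.size(); ++id) {
    if (!asmb.units[id].alive) continue;
    if ((int)asmb.units[id].seq[0].size() >= min_contig_len) keep.push_back(id);
    else unplaced += asmb.units[id].nreads;
  }
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    const std::string &sa = asmb.units[a].seq[0], &sb = asmb.units[b].seq[0];
    if (sa.size() != sb.size()) return sa.size() > sb.size();
    return sa < sb;
  });
  CharacterVector seqs(keep.size());
  IntegerVector nreads(keep.size());
  for (int i = 0; i < (int)keep.size(); ++i) {
    seqs[i] = asmb.units[keep[i]].seq[0];
    nreads[i] = (int)asmb.units[keep[i]].nreads;
  }
  return List::create(_["sequence"] = seqs, _["n_reads"] = nreads,
                      _["unplaced_reads"] = (double)unplaced);
}
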