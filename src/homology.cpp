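// Ungapped local homology searches: seeded nucleotide alignment and
// six-frame translated protein search. Alignments are exact within any
// diagonal that carries a seed (the whole diagonal is rescored by a
// maximal-subarray pass), so seeded results coincide with an exhaustive
// all-diagonal scan whenever the optimum lies on a seeded diagonal.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static const int NT_K = 11;   // nucleotide seed length
static const int AA_K = 5;    // protein seed length

static inline int nt_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;  // N and anything else: never matches
  }
}

static std::string revcomp(const std::string &s) {
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

// best-scoring interval on one diagonal (maximal subarray).
// Ties within the diagonal: earliest start, then earliest end.
struct Interval { long score = LONG_MIN; int q_start = -1, q_end = -1, matches = 0; };

static Interval diag_best_nt(const std::string &q, const std::string &s, int d,
                             int match, int mismatch) {
  // position i in q pairs with i + d in s
  int lo = std::max(0, -d);
  int hi = std::min((int)q.size(), (int)s.size() - d);
  Interval best;
  long cur = 0; int cur_start = lo;
  for (int i = lo; i < hi; ++i) {
    int a = nt_code(q[i]), b = nt_code(s[i + d]);
    int sc = (a < 4 && a == b) ? match : mismatch;
    cur += sc;
    if (cur > best.score) { best.score = cur; best.q_start = cur_start; best.q_end = i + 1; }
    if (cur < 0) { cur = 0; cur_start = i + 1; }
  }
  if (best.q_start >= 0) {
    int m = 0;
    for (int i = best.q_start; i < best.q_end; ++i) {
      int a = nt_code(q[i]), b = nt_code(s[i + d]);
      if (a < 4 && a == b) ++m;
    }
    best.matches = m;
  }
  return best;
}

struct NtHit {
  bool found = false;
  long score = 0; int matches = 0, aln_len = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  int strand = 1;  // +1 / -1
};

// candidate diagonals of (oriented query, subject) sharing an 11-mer
static void seed_diagonals(const std::string &q, const std::string &s,
                           std::unordered_set<int> &diags) {
  int qs = q.size(), ss = s.size();
  if (qs < NT_K || ss < NT_K) return;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  uint64_t key = 0, mask = (1ULL << (2 * NT_K)) - 1;
  int run = 0;
  for (int j = 0; j < ss; ++j) {
    int c = nt_code(s[j]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= NT_K) idx[key].push_back(j - NT_K + 1);
  }
  key = 0; run = 0;
  for (int i = 0; i < qs; ++i) {
    int c = nt_code(q[i]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= NT_K) {
      auto it = idx.find(key);
      if (it != idx.end()) {
        int qi = i - NT_K + 1;
        for (int j : it->second) diags.insert(j - qi);
      }
    }
  }
}

// Better-than comparison under the global tie rule:
// score desc, then lower s_start, then + strand, then lower q_start.
static bool hit_better(long score, int s_start, int strand, int q_start, const NtHit &cur) {
  if (!cur.found) return true;
  if (score != cur.score) return score > cur.score;
  if (s_start != cur.s_start) return s_start < cur.s_start;
  if (strand != cur.strand) return strand > cur.strand;
  return q_start < cur.q_start;
}

static NtHit align_nt(const std::string &query, const std::string &subject,
                      int match, int mismatch, long min_score) {
  NtHit best;
  if (query.empty() || subject.empty()) return best;
  for (int strand = 1; strand >= -1; strand -= 2) {
    std::string q = (strand == 1) ? query : revcomp(query);
    std::unordered_set<int> diags;
    seed_diagonals(q, subject, diags);
    for (int d : diags) {
      Interval iv = diag_best_nt(q, subject, d, match, mismatch);
      if (iv.q_start < 0) continue;
      int s_start = iv.q_start + d;
      if (hit_better(iv.score, s_start, strand, iv.q_start, best)) {
        best.found = true;
        best.score = iv.score; best.matches = iv.matches;
        best.aln_len = iv.q_end - iv.q_start;
        best.q_start = iv.q_start; best.q_end = iv.q_end;
        best.s_start = s_start; best.s_end = iv.q_end + d;
        best.strand = strand;
      }
    }
  }
  if (!best.found || best.score < min_score) { best.found = false; }
  return best;
}

static List hit_to_list(const NtHit &h) {
  if (!h.found) return List::create();
  return List::create(
    _["raw_score"] = (double)h.score, _["matches"] = h.matches,
    _["aln_len"] = h.aln_len,
    _["q_start"] = h.q_start, _["q_end"] = h.q_end,
    _["s_start"] = h.s_start, _["s_end"] = h.s_end,
    _["strand"] = h.strand == 1 ? "+" : "-");
}

// [[Rcpp::export(name = ".align_nt_cpp")]]
List align_nt_cpp(std::string query, std::string subject,
                  int match, int mismatch, int min_score) {
  return hit_to_list(align_nt(query, subject, match, mismatch, min_score));
}

// all (query, subject) best hits with raw score >= min_score.
// One shared 11-mer index over the subjects; per query, seeded diagonals
// are rescored exhaustively, so per-subject results equal align_nt().
// [[Rcpp::export(name = ".search_nt_batch_cpp")]]
DataFrame search_nt_batch_cpp(CharacterVector queries, CharacterVector subjects,
                              int match, int mismatch, int min_score) {
  int ns = subjects.size();
  std::vector<std::string> subs(ns);
  for (int b = 0; b < ns; ++b) subs[b] = as<std::string>(subjects[b]);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx;
  uint64_t mask = (1ULL << (2 * NT_K)) - 1;
  for (int b = 0; b < ns; ++b) {
    uint64_t key = 0; int run = 0;
    for (int j = 0; j < (int)subs[b].size(); ++j) {
      int c = nt_code(subs[b][j]);
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= NT_K) idx[key].emplace_back(b, j - NT_K + 1);
    }
  }
  std::vector<int> qi, si, matches, aln_len, qs, qe, ss, se;
  std::vector<double> score;
  std::vector<std::string> strand;
  std::vector<NtHit> best(ns);
  for (int a = 0; a < queries.size(); ++a) {
    std::string fwd = as<std::string>(queries[a]);
    for (int b = 0; b < ns; ++b) best[b] = NtHit();
    for (int st = 1; st >= -1; st -= 2) {
      std::string q = (st == 1) ? fwd : revcomp(fwd);
      std::unordered_set<int64_t> seen;
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < (int)q.size(); ++i) {
        int c = nt_code(q[i]);
        if (c > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (run + 1 < NT_K) { ++run; continue; }
        ++run;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        int qpos = i - NT_K + 1;
        for (auto &pr : it->second) {
          int b = pr.first, d = pr.second - qpos;
          int64_t dk = ((int64_t)b << 25) ^ ((int64_t)(d + 2000000) << 1) ^
            (st == 1);
          if (!seen.insert(dk).second) continue;
          Interval iv = diag_best_nt(q, subs[b], d, match, mismatch);
          if (iv.q_start < 0) continue;
          int s_start = iv.q_start + d;
          if (hit_better(iv.score, s_start, st, iv.q_start, best[b])) {
            best[b].found = true;
            best[b].score = iv.score; best[b].matches = iv.matches;
            best[b].aln_len = iv.q_end - iv.q_start;
            best[b].q_start = iv.q_start; best[b].q_end = iv.q_end;
            best[b].s_start = s_start; best[b].s_end = iv.q_end + d;
            best[b].strand = st;
          }
        }
      }
    }
    for (int b = 0; b < ns; ++b) {
      if (!best[b].found || best[b].score < min_score) continue;
      const NtHit &h = best[b];
      qi.push_back(a + 1); si.push_back(b + 1);
      score.push_back((double)h.score); matches.push_back(h.matches);
      aln_len.push_back(h.aln_len);
      qs.push_back(h.q_start); qe.push_back(h.q_end);
      ss.push_back(h.s_start); se.push_back(h.s_end);
      strand.push_back(h.strand == 1 ? "+" : "-");
    }
  }
  return DataFrame::create(
    _["query"] = qi, _["subject"] = si, _["raw_score"] = score,
    _["matches"] = matches, _["aln_len"] = aln_len,
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = strand, _["stringsAsFactors"] = false);
}

// Assign each read to its unique best reference sequence (both strands).
// tie = another reference reaches the same best score.
// [[Rcpp::export(name = ".assign_reads_nt_cpp")]]
List assign_reads_nt_cpp(CharacterVector reads, CharacterVector refs,
                         int match, int mismatch, int min_score) {
  int nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(refs[i]);
  // global 11-mer index over references
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx;
  uint64_t mask = (1ULL << (2 * NT_K)) - 1;
  for (int r = 0; r < nr; ++r) {
    uint64_t key = 0; int run = 0;
    for (int j = 0; j < (int)rs[r].size(); ++j) {
      int c = nt_code(rs[r][j]);
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= NT_K) idx[key].emplace_back(r, j - NT_K + 1);
    }
  }
  int n = reads.size();
  IntegerVector best_ref(n), best_score(n);
  LogicalVector tie(n);
  for (int a = 0; a < n; ++a) {
    std::string fwd = as<std::string>(reads[a]);
    long top = LONG_MIN; int top_ref = -1; bool top_tie = false;
    std::unordered_map<int, long> ref_best;
    for (int strand = 1; strand >= -1; strand -= 2) {
      std::string q = (strand == 1) ? fwd : revcomp(fwd);
      std::unordered_set<int64_t> seen;
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < (int)q.size(); ++i) {
        int c = nt_code(q[i]);
        if (c > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (run + 1 < NT_K) { ++run; continue; }
        ++run;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        int qi = i - NT_K + 1;
        for (auto &pr : it->second) {
          int r = pr.first, d = pr.second - qi;
          int64_t dk = ((int64_t)r << 24) ^ ((int64_t)(d + 1000000) << 1) ^ (strand == 1);
          if (!seen.insert(dk).second) continue;
          Interval iv = diag_best_nt(q, rs[r], d, match, mismatch);
          if (iv.q_start < 0) continue;
          auto rb = ref_best.find(r);
          if (rb == ref_best.end() || iv.score > rb->second) ref_best[r] = iv.score;
        }
      }
    }
    for (auto &kv : ref_best) {
      if (kv.second > top) { top = kv.second; top_ref = kv.first; top_tie = false; }
      else if (kv.second == top && kv.first != top_ref) top_tie = true;
    }
    if (top_ref >= 0 && top >= min_score) {
      best_ref[a] = top_ref + 1; best_score[a] = (int)top; tie[a] = top_tie;
    } else {
      best_ref[a] = NA_INTEGER; best_score[a] = NA_INTEGER; tie[a] = false;
    }
  }
  return List::create(_["ref"] = best_ref, _["score"] = best_score, _["tie"] = tie);
}

// ---------------------------------------------------------------------------
// translated search
// ---------------------------------------------------------------------------

// standard genetic code, TCAG codon order
static const char *GENETIC_CODE =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int tcag(char c) {
  switch (c) {
  case 'T': return 0; case 'C': return 1; case 'A': return 2; case 'G': return 3;
  default: return -1;
  }
}

static std::string translate_frame(const std::string &nt, int offset) {
  std::string aa;
  for (size_t i = offset; i + 2 < nt.size(); i += 3) {
    int a = tcag(nt[i]), b = tcag(nt[i + 1]), c = tcag(nt[i + 2]);
    aa.push_back((a < 0 || b < 0 || c < 0) ? 'X' : GENETIC_CODE[a * 16 + b * 4 + c]);
  }
  return aa;
}

// [[Rcpp::export(name = ".translate_cpp")]]
CharacterVector translate_cpp(CharacterVector seqs, int offset) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = translate_frame(as<std::string>(seqs[i]), offset);
  return out;
}

// BLOSUM62, NCBI order ARNDCQEGHILKMFPSTWYVBZX*
static const char *AA_ORDER = "ARNDCQEGHILKMFPSTWYVBZX*";
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
static const int STOP_PENALTY = -1000;  // stops break alignments

static int aa_idx_tab[128];
static bool aa_tab_init = false;
static void init_aa_tab() {
  if (aa_tab_init) return;
  for (int i = 0; i < 128; ++i) aa_idx_tab[i] = 22;  // unknown -> X
  for (int i = 0; i < 24; ++i) aa_idx_tab[(int)AA_ORDER[i]] = i;
  aa_tab_init = true;
}
static inline int aa_idx(char c) { return aa_idx_tab[(int)(unsigned char)c]; }
static inline int aa_score(char a, char b) {
  if (a == '*' || b == '*') return STOP_PENALTY;
  return BLOSUM62[aa_idx(a)][aa_idx(b)];
}

struct AaInterval { long score = LONG_MIN; int q_start = -1, q_end = -1, matches = 0; };

static AaInterval diag_best_aa(const std::string &q, const std::string &s, int d) {
  int lo = std::max(0, -d);
  int hi = std::min((int)q.size(), (int)s.size() - d);
  AaInterval best;
  long cur = 0; int cur_start = lo;
  for (int i = lo; i < hi; ++i) {
    cur += aa_score(q[i], s[i + d]);
    if (cur > best.score) { best.score = cur; best.q_start = cur_start; best.q_end = i + 1; }
    if (cur < 0) { cur = 0; cur_start = i + 1; }
  }
  if (best.q_start >= 0) {
    int m = 0;
    for (int i = best.q_start; i < best.q_end; ++i) if (q[i] == s[i + d]) ++m;
    best.matches = m;
  }
  return best;
}

// frames ordered +1,+2,+3,-1,-2,-3 (index 0..5); labels +/-1..3
static int frame_label(int order_idx) {
  return (order_idx < 3) ? (order_idx + 1) : -(order_idx - 2);
}

struct AaHit {
  bool found = false;
  long score = 0; int subject = -1, frame_idx = 0;
  int matches = 0, aln_len = 0, q_start = 0, q_end = 0, s_start = 0, s_end = 0;
};

// Batched six-frame translated search against a protein database.
// lex_rank: 1-based lexicographic rank of each subject id (tie-break).
// tie = another subject reaches the same best score.
// [[Rcpp::export(name = ".translated_best_hits_cpp")]]
List translated_best_hits_cpp(CharacterVector reads, CharacterVector proteins,
                              IntegerVector lex_rank, int min_score) {
  init_aa_tab();
  int np = proteins.size();
  std::vector<std::string> ps(np);
  for (int i = 0; i < np; ++i) ps[i] = as<std::string>(proteins[i]);
  // 5-mer index over proteins (standard residues only), rolling base-25 key
  const uint32_t P4 = 390625u;  // 25^4
  std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> idx;
  for (int p = 0; p < np; ++p) {
    const std::string &s = ps[p];
    uint32_t key = 0; int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int v = aa_idx(s[j]);
      if (v >= 20 || s[j] == '*') { run = 0; key = 0; continue; }
      key = (key % P4) * 25 + (uint32_t)v;
      if (++run >= AA_K) idx[key].emplace_back(p, j - AA_K + 1);
    }
  }
  int n = reads.size();
  IntegerVector subject(n), score(n), frame(n), matches(n), aln_len(n),
    qs(n), qe(n), ss(n), se(n);
  LogicalVector tie(n);
  for (int a = 0; a < n; ++a) {
    std::string fwd = as<std::string>(reads[a]);
    std::string rev = revcomp(fwd);
    AaHit best;
    std::unordered_map<int, long> subj_best;
    for (int f = 0; f < 6; ++f) {
      const std::string &src = (f < 3) ? fwd : rev;
      std::string q = translate_frame(src, f % 3);
      if ((int)q.size() < AA_K) continue;
      std::unordered_set<int64_t> seen;
      uint32_t key = 0; int run = 0;
      for (int j = 0; j < (int)q.size(); ++j) {
        int v = aa_idx(q[j]);
        if (v >= 20 || q[j] == '*') { run = 0; key = 0; continue; }
        key = (key % P4) * 25 + (uint32_t)v;
        if (run + 1 < AA_K) { ++run; continue; }
        ++run;
        int i = j - AA_K + 1;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (auto &pr : it->second) {
          int p = pr.first, d = pr.second - i;
          int64_t dk = ((int64_t)p << 20) ^ (int64_t)(d + 100000);
          if (!seen.insert(dk).second) continue;
          AaInterval iv = diag_best_aa(q, ps[p], d);
          if (iv.q_start < 0) continue;
          auto sb = subj_best.find(p);
          if (sb == subj_best.end() || iv.score > sb->second) subj_best[p] = iv.score;
          // better-than: score desc, subject lex rank asc, frame order asc, s_start asc
          bool better;
          if (!best.found) better = true;
          else if (iv.score != best.score) better = iv.score > best.score;
          else if (lex_rank[p] != lex_rank[best.subject])
            better = lex_rank[p] < lex_rank[best.subject];
          else if (f != best.frame_idx) better = f < best.frame_idx;
          else better = (iv.q_start + d) < best.s_start;
          if (better) {
            best.found = true; best.score = iv.score; best.subject = p;
            best.frame_idx = f; best.matches = iv.matches;
            best.aln_len = iv.q_end - iv.q_start;
            best.q_start = iv.q_start; best.q_end = iv.q_end;
            best.s_start = iv.q_start + d; best.s_end = iv.q_end + d;
          }
        }
      }
    }
    if (best.found && best.score >= min_score) {
      bool t = false;
      for (auto &kv : subj_best)
        if (kv.first != best.subject && kv.second == best.score) t = true;
      subject[a] = best.subject + 1; score[a] = (int)best.score;
      frame[a] = frame_label(best.frame_idx);
      matches[a] = best.matches; aln_len[a] = best.aln_len;
      qs[a] = best.q_start; qe[a] = best.q_end;
      ss[a] = best.s_start; se[a] = best.s_end;
      tie[a] = t;
    } else {
      subject[a] = NA_INTEGER; score[a] = NA_INTEGER; frame[a] = NA_INTEGER;
      matches[a] = NA_INTEGER; aln_len[a] = NA_INTEGER;
      qs[a] = NA_INTEGER; qe[a] = NA_INTEGER; ss[a] = NA_INTEGER; se[a] = NA_INTEGER;
      tie[a] = false;
    }
  }
  return List::create(
    _["subject"] = subject, _["raw_score"] = score, _["tie"] = tie,
    _["frame"] = frame, _["matches"] = matches, _["aln_len"] = aln_len,
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
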