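// Core of the paired-end mapper and pileup accumulator: hashed k-mer seed
// index, local Smith-Waterman with affine gaps, concordant pair selection,
// and per-base pileup counting from CIGAR-style placements.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

inline int encodeBase(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

inline char complementBase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

std::string reverseComplement(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complementBase(c);
  return r;
}

struct Scoring {
  int match, mismatch, gapOpen, gapExtend;
};

struct Aln {
  int score = 0;
  int tstart = 0, tend = 0;   // 0-based, half-open on the target window
  int qstart = 0, qend = 0;   // 0-based, half-open on the query
  int ngaps = 0;
  std::string cigar;          // run-length ops over {=,X,I,D,S}
};

void appendOp(std::string& cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

// Full (unbanded) local alignment with affine gaps; a gap of length g costs
// gapOpen + (g-1)*gapExtend.  Deterministic: the first maximal cell in
// row-major order is chosen, and traceback prefers diagonal moves.
Aln swAlign(const std::string& q, const std::string& t, const Scoring& sc) {
  const int m = (int)q.size(), n = (int)t.size();
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[at(i, j)] = std::max(H[at(i, j - 1)] + sc.gapOpen,
                             E[at(i, j - 1)] + sc.gapExtend);
      F[at(i, j)] = std::max(H[at(i - 1, j)] + sc.gapOpen,
                             F[at(i - 1, j)] + sc.gapExtend);
      int s = (q[i - 1] == t[j - 1]) ? sc.match : sc.mismatch;
      int h = H[at(i - 1, j - 1)] + s;
      h = std::max(h, E[at(i, j)]);
      h = std::max(h, F[at(i, j)]);
      h = std::max(h, 0);
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  Aln out;
  out.score = best;
  if (best <= 0) return out;

  std::vector<char> ops;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H[at(i, j)];
      if (h == 0) break;
      int s = (q[i - 1] == t[j - 1]) ? sc.match : sc.mismatch;
      if (h == H[at(i - 1, j - 1)] + s) {
        ops.push_back(q[i - 1] == t[j - 1] ? '=' : 'X');
        --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {           // gap consuming target: deletion
      ops.push_back('D');
      ++out.ngaps;
      if (E[at(i, j)] == H[at(i, j - 1)] + sc.gapOpen) state = 'H';
      --j;
    } else {                             // gap consuming query: insertion
      ops.push_back('I');
      ++out.ngaps;
      if (F[at(i, j)] == H[at(i - 1, j)] + sc.gapOpen) state = 'H';
      --i;
    }
  }
  out.qstart = i; out.tstart = j;
  out.qend = bi;  out.tend = bj;

  std::reverse(ops.begin(), ops.end());
  std::string cig;
  appendOp(cig, 'S', out.qstart);
  size_t p = 0;
  while (p < ops.size()) {
    size_t p2 = p;
    while (p2 < ops.size() && ops[p2] == ops[p]) ++p2;
    appendOp(cig, ops[p], (int)(p2 - p));
    p = p2;
  }
  appendOp(cig, 'S', m - out.qend);
  out.cigar = cig;
  return out;
}

struct SeedIndex {
  int k = 0;
  std::unordered_map<uint64_t, std::vector<int>> table;
};

void buildSeedIndex(const std::string& ref, int k, SeedIndex& idx) {
  idx.k = k;
  idx.table.clear();
  uint64_t key = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < (int)ref.size(); ++i) {
    int e = encodeBase(ref[i]);
    if (e < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    ++valid;
    if (valid >= k) idx.table[key].push_back(i - k + 1);
  }
}

// Seed the read every `step` bases (plus the final window) and vote for the
// implied target offsets; returns (offset, seed-hit count) sorted by votes.
std::vector<std::pair<int, int>> seedCandidates(const std::string& read,
                                                const SeedIndex& idx,
                                                int step, int maxCand) {
  const int k = idx.k, m = (int)read.size();
  std::vector<std::pair<int, int>> out;
  if (m < k) return out;
  std::unordered_map<int, int> votes;
  std::vector<int> starts;
  for (int s = 0; s + k <= m; s += step) starts.push_back(s);
  if (starts.empty() || starts.back() != m - k) starts.push_back(m - k);
  for (int s : starts) {
    uint64_t key = 0;
    bool ok = true;
    for (int x = 0; x < k; ++x) {
      int e = encodeBase(read[s + x]);
      if (e < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)e;
    }
    if (!ok) continue;
    auto it = idx.table.find(key);
    if (it == idx.table.end()) continue;
    for (int o : it->second) votes[o - s] += 1;
  }
  out.assign(votes.begin(), votes.end());
  std::sort(out.begin(), out.end(), [](const std::pair<int, int>& a,
                                       const std::pair<int, int>& b) {
    return a.second != b.second ? a.second > b.second : a.first < b.first;
  });
  if ((int)out.size() > maxCand) out.resize(maxCand);
  return out;
}

struct Placement {
  bool mapped = false;
  int tstart = 0, tend = 0;
  int score = 0, ngaps = 0;
  char strand = '+';
  std::string cigar;
  std::string oseq;   // read sequence oriented to the forward target strand
};

std::vector<Placement> placeRead(const std::string& read, const std::string& ref,
                                 const SeedIndex& idx, int step, int maxCand,
                                 const Scoring& sc, int pad, int minScore) {
  std::vector<Placement> out;
  const int L = (int)ref.size(), m = (int)read.size();
  for (int si = 0; si < 2; ++si) {
    const char strand = si == 0 ? '+' : '-';
    const std::string oriented = si == 0 ? read : reverseComplement(read);
    auto cands = seedCandidates(oriented, idx, step, maxCand);
    for (auto& c : cands) {
      int ws = std::max(0, c.first - pad);
      int we = std::min(L, c.first + m + pad);
      if (we <= ws) continue;
      Aln a = swAlign(oriented, ref.substr(ws, we - ws), sc);
      if (a.score < minScore) continue;
      Placement p;
      p.mapped = true;
      p.tstart = ws + a.tstart;
      p.tend = ws + a.tend;
      p.score = a.score;
      p.ngaps = a.ngaps;
      p.strand = strand;
      p.cigar = a.cigar;
      p.oseq = oriented;
      out.push_back(p);
    }
  }
  // deduplicate identical placements reached from different seeds
  std::sort(out.begin(), out.end(), [](const Placement& a, const Placement& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.tstart != b.tstart) return a.tstart < b.tstart;
    return a.strand < b.strand;
  });
  out.erase(std::unique(out.begin(), out.end(),
                        [](const Placement& a, const Placement& b) {
                          return a.tstart == b.tstart && a.strand == b.strand &&
                                 a.cigar == b.cigar;
                        }),
            out.end());
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw(std::string read, std::string window, int match, int mismatch,
            int gap_open, int gap_extend) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  Aln a = swAlign(read, window, sc);
  return List::create(_["score"] = a.score, _["target_start"] = a.tstart,
                      _["target_end"] = a.tend, _["query_start"] = a.qstart,
                      _["query_end"] = a.qend, _["cigar"] = a.cigar,
                      _["n_gaps"] = a.ngaps);
}

// [[Rcpp::export]]
List cpp_index_table(std::string ref, int k) {
  SeedIndex idx;
  buildSeedIndex(ref, k, idx);
  const char* bases = "ACGT";
  int n = (int)idx.table.size();
  CharacterVector keys(n);
  List vals(n);
  int tot = 0, i = 0;
  for (auto& kv : idx.table) {
    std::string kmer(k, 'A');
    uint64_t key = kv.first;
    for (int x = k - 1; x >= 0; --x) {
      kmer[x] = bases[key & 3ULL];
      key >>= 2;
    }
    keys[i] = kmer;
    std::vector<int> off = kv.second;
    std::sort(off.begin(), off.end());
    vals[i] = wrap(off);
    tot += (int)off.size();
    ++i;
  }
  vals.attr("names") = keys;
  return List::create(_["table"] = vals, _["n_stored"] = tot);
}

// [[Rcpp::export]]
DataFrame cpp_candidates(std::string ref, int k, int step, std::string read,
                         int max_candidates) {
  SeedIndex idx;
  buildSeedIndex(ref, k, idx);
  auto fwd = seedCandidates(read, idx, step, max_candidates);
  auto rev = seedCandidates(reverseComplement(read), idx, step, max_candidates);
  std::vector<int> off;
  std::vector<int> hits;
  std::vector<std::string> strand;
  for (auto& c : fwd) { off.push_back(c.first); hits.push_back(c.second); strand.push_back("+"); }
  for (auto& c : rev) { off.push_back(c.first); hits.push_back(c.second); strand.push_back("-"); }
  return DataFrame::create(_["offset"] = off, _["hits"] = hits,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_map_pairs(std::string ref, CharacterVector names,
                        CharacterVector reads1, CharacterVector reads2, int k,
                        int step, int max_candidates, int match, int mismatch,
                        int gap_open, int gap_extend, int frag_min,
                        int frag_max, int pad, int min_score) {
  SeedIndex idx;
  buildSeedIndex(ref, k, idx);
  Scoring sc{match, mismatch, gap_open, gap_extend};
  const int np = names.size();

  std::vector<std::string> o_name;
  std::vector<int> o_mate, o_pos, o_score;
  std::vector<std::string> o_strand, o_cigar, o_seq;
  std::vector<bool> o_mapped, o_concordant;

  for (int r = 0; r < np; ++r) {
    std::string nm = as<std::string>(names[r]);
    std::string r1 = as<std::string>(reads1[r]);
    std::string r2 = as<std::string>(reads2[r]);
    auto p1 = placeRead(r1, ref, idx, step, max_candidates, sc, pad, min_score);
    auto p2 = placeRead(r2, ref, idx, step, max_candidates, sc, pad, min_score);

    int b1 = -1, b2 = -1;
    bool concordant = false;
    long bestSum = -1;
    int bestStart = 1 << 30;
    for (int i = 0; i < (int)p1.size(); ++i) {
      for (int j = 0; j < (int)p2.size(); ++j) {
        if (p1[i].strand == p2[j].strand) continue;
        int lo = std::min(p1[i].tstart, p2[j].tstart);
        int hi = std::max(p1[i].tend, p2[j].tend);
        int frag = hi - lo;
        if (frag < frag_min || frag > frag_max) continue;
        long sum = (long)p1[i].score + p2[j].score;
        if (sum > bestSum || (sum == bestSum && lo < bestStart)) {
          bestSum = sum; bestStart = lo; b1 = i; b2 = j; concordant = true;
        }
      }
    }
    if (!concordant) {
      if (!p1.empty()) b1 = 0;
      if (!p2.empty()) b2 = 0;
    }

    const Placement* sel[2] = {b1 >= 0 ? &p1[b1] : nullptr,
                               b2 >= 0 ? &p2[b2] : nullptr};
    for (int mte = 0; mte < 2; ++mte) {
      o_name.push_back(nm);
      o_mate.push_back(mte + 1);
      if (sel[mte]) {
        const Placement& p = *sel[mte];
        o_mapped.push_back(true);
        o_pos.push_back(p.tstart);
        o_strand.push_back(std::string(1, p.strand));
        o_score.push_back(p.score);
        o_cigar.push_back(p.cigar);
        o_seq.push_back(p.oseq);
      } else {
        o_mapped.push_back(false);
        o_pos.push_back(NA_INTEGER);
        o_strand.push_back("*");
        o_score.push_back(0);
        o_cigar.push_back("*");
        o_seq.push_back("");
      }
      o_concordant.push_back(concordant);
    }
  }

  return DataFrame::create(
      _["read"] = o_name, _["mate"] = o_mate, _["mapped"] = o_mapped,
      _["pos"] = o_pos, _["strand"] = o_strand, _["score"] = o_score,
      _["cigar"] = o_cigar, _["seq"] = o_seq, _["concordant"] = o_concordant,
      _["stringsAsFactors"] = false);
}

// Pileup accumulation from placements.  `pos` is 0-based target start, `seq`
// the forward-oriented read; counts rows are A,C,G,T,DEL.  Insertions are
// anchored to the column immediately preceding the inserted bases.
// [[Rcpp::export]]
List cpp_pileup(int ref_length, IntegerVector pos, CharacterVector cigar,
                CharacterVector seq) {
  IntegerMatrix counts(5, ref_length);
  IntegerVector insCount(ref_length);
  std::vector<int> insCol, delStart, delLen;
  std::vector<std::string> insSeq;
  int rejected = 0;

  for (int r = 0; r < pos.size(); ++r) {
    if (pos[r] == NA_INTEGER) continue;
    std::string cig = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    int t = pos[r], qi = 0;
    bool bad = (t < 0);

    // first pass: bounds check so a bad placement leaves no partial counts
    {
      int tt = t;
      size_t p = 0;
      while (p < cig.size() && !bad) {
        int len = 0;
        while (p < cig.size() && isdigit(cig[p])) len = len * 10 + (cig[p++] - '0');
        char op = cig[p++];
        if (op == '=' || op == 'X' || op == 'M' || op == 'D') tt += len;
        if (tt > ref_length) bad = true;
      }
    }
    if (bad) { ++rejected; continue; }

    size_t p = 0;
    while (p < cig.size()) {
      int len = 0;
      while (p < cig.size() && isdigit(cig[p])) len = len * 10 + (cig[p++] - '0');
      char op = cig[p++];
      if (op == 'S') {
        qi += len;
      } else if (op == '=' || op == 'X' || op == 'M') {
        for (int x = 0; x < len; ++x) {
          int e = encodeBase(sq[qi]);
          if (e >= 0) counts(e, t) += 1;
          ++t; ++qi;
        }
      } else if (op == 'D') {
        delStart.push_back(t);
        delLen.push_back(len);
        for (int x = 0; x < len; ++x) { counts(4, t) += 1; ++t; }
      } else if (op == 'I') {
        if (t > 0) {
          insCount[t - 1] += 1;
          insCol.push_back(t - 1);
          insSeq.push_back(sq.substr(qi, len));
        }
        qi += len;
      }
    }
  }

  return List::create(
      _["counts"] = counts, _["ins_count"] = insCount,
      _["ins_events"] = DataFrame::create(_["col"] = insCol, _["seq"] = insSeq,
                                          _["stringsAsFactors"] = false),
      _["del_events"] = DataFrame::create(_["start"] = delStart,
                                          _["len"] = delLen),
      _["rejected"] = rejected);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = reverseComplement(as<std::string>(x[i]));
  return out;
}
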