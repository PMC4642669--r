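#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything that is not A/C/G/T
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
  case 'A': return 'T'; case 'a': return 't';
  case 'C': return 'G'; case 'c': return 'g';
  case 'G': return 'C'; case 'g': return 'c';
  case 'T': return 'A'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// Concatenated-reference index: global coordinates with per-sequence offsets.
// K-mers spanning a sequence boundary are never inserted because insertion is
// done per sequence.
struct RefIndex {
  std::string cat;                 // concatenated sequences
  std::vector<size_t> offset;      // start of each sequence in cat
  std::vector<size_t> len;         // length of each sequence
  int k;
  std::unordered_map<uint64_t, std::vector<uint32_t> > pos; // kmer -> global starts
};

static bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static void build_index(RefIndex &idx, const std::vector<std::string> &refs, int k) {
  idx.k = k;
  size_t total = 0;
  for (size_t i = 0; i < refs.size(); ++i) total += refs[i].size();
  idx.cat.reserve(total);
  for (size_t i = 0; i < refs.size(); ++i) {
    idx.offset.push_back(idx.cat.size());
    idx.len.push_back(refs[i].size());
    idx.cat += refs[i];
  }
  for (size_t i = 0; i < refs.size(); ++i) {
    if ((int)refs[i].size() < k) continue;
    const char *s = idx.cat.c_str() + idx.offset[i];
    for (size_t j = 0; j + k <= refs[i].size(); ++j) {
      uint64_t key;
      if (encode_kmer(s + j, k, key))
        idx.pos[key].push_back((uint32_t)(idx.offset[i] + j));
    }
  }
}

// Which sequence does global position g fall in? Binary search over offsets.
static int seq_of(const RefIndex &idx, size_t g) {
  int lo = 0, hi = (int)idx.offset.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (idx.offset[mid] <= g) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// Hamming distance with early abort once it exceeds cap.
static int hamming_capped(const char *a, const char *b, int L, int cap) {
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i]) {
      if (++d > cap) return d;
    }
  }
  return d;
}

struct Candidate {
  uint32_t gpos;
  uint8_t strand; // 0 forward, 1 reverse
  bool operator<(const Candidate &o) const {
    if (gpos != o.gpos) return gpos < o.gpos;
    return strand < o.strand;
  }
  bool operator==(const Candidate &o) const {
    return gpos == o.gpos && strand == o.strand;
  }
};

// Map reads by exact-seed anchoring and Hamming extension.
//
// For each read of length L with mismatch budget m = floor(rate * L), m + 1
// block seeds of length min(max_seed, floor(L / (m + 1))) are spread evenly
// across the read, so any placement with <= m mismatches must match at least
// one seed exactly (pigeonhole). The minimal-mismatch placement among the
// anchored candidates is reported; ties on the minimum are broken toward the
// lowest (sequence, coordinate, forward-before-reverse) and flagged through
// n_best > 1.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reference, CharacterVector reads,
                        double rate, int max_seed = 31) {
  std::vector<std::string> refs;
  refs.reserve(reference.size());
  for (R_xlen_t i = 0; i < reference.size(); ++i)
    refs.push_back(as<std::string>(reference[i]));

  // One index per distinct seed length actually needed (reads may vary in L).
  std::unordered_map<int, RefIndex> indexes;

  R_xlen_t n = reads.size();
  IntegerVector out_ref(n, NA_INTEGER), out_pos(n, NA_INTEGER),
      out_mm(n, NA_INTEGER), out_nbest(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    if (L < 1) continue;
    int m = (int)std::floor(rate * (double)L + 1e-9);
    if (m >= L) m = L - 1;
    int s = std::min(max_seed, L / (m + 1));
    if (s < 1) s = 1;

    RefIndex &idx = [&]() -> RefIndex & {
      auto it = indexes.find(s);
      if (it != indexes.end()) return it->second;
      RefIndex &nw = indexes[s];
      build_index(nw, refs, s);
      return nw;
    }();

    std::string rev = revcomp(fwd);
    const std::string *ori[2] = { &fwd, &rev };

    std::vector<Candidate> cands;
    for (int o = 0; o < 2; ++o) {
      const char *rd = ori[o]->c_str();
      for (int j = 0; j <= m; ++j) {
        int off = (m == 0) ? 0 : (int)(( (long long)j * (L - s) ) / m);
        uint64_t key;
        if (!encode_kmer(rd + off, s, key)) continue;
        auto it = idx.pos.find(key);
        if (it == idx.pos.end()) continue;
        for (uint32_t hp : it->second) {
          if ((long long)hp - off < 0) continue;
          uint32_t start = hp - (uint32_t)off;
          int sq = seq_of(idx, start);
          if (start + (uint32_t)L > idx.offset[sq] + idx.len[sq]) continue;
          Candidate c; c.gpos = start; c.strand = (uint8_t)o;
          cands.push_back(c);
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best = m + 1, nbest = 0;
    Candidate bestc; bestc.gpos = 0; bestc.strand = 0;
    for (const Candidate &c : cands) {
      const char *rd = ori[c.strand]->c_str();
      int cap = best; // allow equality detection for tie counting
      int d = hamming_capped(idx.cat.c_str() + c.gpos, rd, L, cap);
      if (d > m) continue;
      if (d < best) {
        best = d; nbest = 1; bestc = c;
      } else if (d == best) {
        ++nbest;
      }
    }
    if (nbest == 0) continue;
    int sq = seq_of(indexes[s], bestc.gpos);
    out_ref[i] = sq + 1;
    out_pos[i] = (int)(bestc.gpos - indexes[s].offset[sq]);
    out_strand[i] = bestc.strand == 0 ? "+" : "-";
    out_mm[i] = best;
    out_nbest[i] = nbest;
  }

  return DataFrame::create(_["ref"] = out_ref, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["mismatches"] = out_mm,
                           _["n_best"] = out_nbest,
                           _["stringsAsFactors"] = false);
}

// Enumerate per-base mismatches of given alignments against the reference.
// Reads are supplied in sequenced orientation; reverse-strand reads are
// reverse complemented before comparison. Returned positions are 0-based on
// the mapped sequence; read_base is the base the read places at that position
// (reference orientation).
// [[Rcpp::export]]
DataFrame cpp_mismatch_events(CharacterVector reference, CharacterVector reads,
                              IntegerVector ref_idx, IntegerVector pos,
                              CharacterVector strand) {
  std::vector<std::string> refs;
  refs.reserve(reference.size());
  for (R_xlen_t i = 0; i < reference.size(); ++i)
    refs.push_back(as<std::string>(reference[i]));

  std::vector<int> ev_aln, ev_ref, ev_pos;
  std::vector<std::string> ev_base, ev_refbase;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (IntegerVector::is_na(ref_idx[i]) || IntegerVector::is_na(pos[i]))
      continue;
    std::string rd = as<std::string>(reads[i]);
    std::string st = as<std::string>(strand[i]);
    if (st == "-") rd = revcomp(rd);
    int ri = ref_idx[i] - 1;
    if (ri < 0 || ri >= (int)refs.size())
      stop("alignment %d refers to a sequence not in the reference", (int)i + 1);
    const std::string &ref = refs[ri];
    int p = pos[i];
    if (p < 0 || p + (int)rd.size() > (int)ref.size())
      stop("alignment %d extends beyond its reference sequence", (int)i + 1);
    for (int j = 0; j < (int)rd.size(); ++j) {
      char a = ref[p + j], b = rd[j];
      if (a != b) {
        ev_aln.push_back((int)i + 1);
        ev_ref.push_back(ri + 1);
        ev_pos.push_back(p + j);
        ev_base.push_back(std::string(1, b));
        ev_refbase.push_back(std::string(1, a));
      }
    }
  }

  return DataFrame::create(_["aln"] = ev_aln, _["ref"] = ev_ref,
                           _["pos"] = ev_pos, _["read_base"] = ev_base,
                           _["ref_base"] = ev_refbase,
                           _["stringsAsFactors"] = false);
}
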