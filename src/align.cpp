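#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Nucleotide codes: A=0 C=1 G=2 T=3 N=4 (anything else -> N)
static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static void encode_seq(const std::string &s, std::vector<int> &out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = nt_code(s[i]);
}

// Banded pairwise alignment.
// mode 0: global (both sequences end-to-end).
// mode 1: glocal/fit (pattern `a` end-to-end, subject `b` ends free).
// Scoring: match +2, mismatch -2, gap -3 (linear); N columns score 0 and are
// excluded from the identity denominator.
// Returns matches, block_len (alignment columns over the used subject span),
// n_excluded (columns touching N), subject span [t_start, t_end) (0-based,
// half-open), and run-length encoded operations over the alignment:
// op 0 = match, 1 = mismatch, 2 = insertion (base(s) in b absent from a),
// 3 = deletion (base(s) in a absent from b).
// [[Rcpp::export(name = ".cpp_band_align")]]
List cpp_band_align(std::string a, std::string b, double band_frac = 0.2,
                    int mode = 0) {
  std::vector<int> av, bv;
  encode_seq(a, av);
  encode_seq(b, bv);
  const int na = (int)av.size(), nb = (int)bv.size();
  const int MATCH = 2, MISMATCH = -2, GAP = -3;
  const int NEG = INT_MIN / 4;

  if (na == 0 || nb == 0) {
    // degenerate: all-gap alignment
    IntegerMatrix ops(na > 0 || nb > 0 ? 1 : 0, 2);
    int block = 0;
    if (na > 0) { ops(0, 0) = 3; ops(0, 1) = na; block = na; }
    else if (nb > 0) { ops(0, 0) = 2; ops(0, 1) = nb; block = (mode == 0) ? nb : 0; }
    return List::create(_["matches"] = 0, _["block_len"] = block,
                        _["n_excluded"] = 0, _["t_start"] = 0,
                        _["t_end"] = (mode == 0) ? nb : 0,
                        _["ops"] = ops, _["score"] = 0);
  }

  int maxlen = std::max(na, nb);
  int half = std::max(10, (int)std::ceil(band_frac * maxlen));
  int dlo, dhi;
  if (mode == 0) {
    dlo = std::min(0, nb - na) - half;
    dhi = std::max(0, nb - na) + half;
  } else {
    dlo = -half;
    dhi = (nb - na) + half; // subject at least reachable anywhere
    if (dhi < half) dhi = half;
  }
  if (dlo < -na) dlo = -na;
  if (dhi > nb) dhi = nb;
  const int W = dhi - dlo + 1;

  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> tb((size_t)(na + 1) * W, 255); // 0 diag,1 up,2 left,4 origin

  // row i = 0
  for (int w = 0; w < W; ++w) {
    int j = 0 + dlo + w;
    if (j < 0 || j > nb) continue;
    if (mode == 0) prev[w] = GAP * j;
    else prev[w] = 0;
    tb[w] = (j == 0) ? 4 : 2;
    if (mode == 1) tb[w] = 4; // free leading subject gap: origin
  }

  // NEG is a "soft" -inf: adding GAP repeatedly must not wrap, and cells
  // outside the band must never win a max
  for (int i = 1; i <= na; ++i) {
    int *cp = cur.data();
    const int *pp = prev.data();
    uint8_t *tbr = tb.data() + (size_t)i * W;
    const int ca = av[i - 1];
    const int *bvp = bv.data() + (i + dlo - 1);
    // valid j range for this row: j in [max(1, i+dlo), min(nb, i+dhi)]
    int wlo = (i + dlo < 0) ? -(i + dlo) : 0;
    int whi = (i + dhi > nb) ? (nb - i - dlo) : (W - 1);
    // flank sentinels so stale values never leak into the max
    if (wlo > 0) cp[wlo - 1] = NEG;
    if (whi < W - 1) cp[whi + 1] = NEG;
    int w = wlo;
    if (i + dlo + w == 0) {  // j == 0 cell: forced pattern gap
      cp[w] = GAP * i;
      tbr[w] = 1;
      ++w;
    } else if (w == 0) {
      // first storage column: the left neighbor lies outside the band
      const int cb = bvp[0];
      const int sub = (ca == 4 || cb == 4) ? 0 : (ca == cb ? MATCH : MISMATCH);
      const int d = pp[0] + sub;
      const int u = (W > 1 ? pp[1] : NEG) + GAP;
      int best = d; uint8_t dir = 0;
      if (u > best) { best = u; dir = 1; }
      cp[0] = best;
      tbr[0] = dir;
      ++w;
    }
    const int wmid = (whi < W - 1) ? whi : (W - 2);
    for (; w <= wmid; ++w) {
      const int cb = bvp[w];
      const int sub = (ca == 4 || cb == 4) ? 0 : (ca == cb ? MATCH : MISMATCH);
      const int d = pp[w] + sub;
      const int u = pp[w + 1] + GAP;
      const int l = cp[w - 1] + GAP;
      int best = d; uint8_t dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cp[w] = best;
      tbr[w] = dir;
    }
    if (w == W - 1 && w <= whi) {  // last band column: no up-neighbor
      const int cb = bvp[w];
      const int sub = (ca == 4 || cb == 4) ? 0 : (ca == cb ? MATCH : MISMATCH);
      const int d = pp[w] + sub;
      const int l = cp[w - 1] + GAP;
      int best = d; uint8_t dir = 0;
      if (l > best) { best = l; dir = 2; }
      cp[w] = best;
      tbr[w] = dir;
    }
    std::swap(prev, cur);
  }

  // locate end cell
  int end_j;
  int score;
  if (mode == 0) {
    end_j = nb;
    int w = nb - na - dlo;
    if (w < 0 || w >= W) stop("alignment band too narrow for these lengths");
    score = prev[w];
  } else {
    int bw = -1; int bs = NEG;
    for (int w = 0; w < W; ++w) {
      int j = na + dlo + w;
      if (j < 0 || j > nb) continue;
      if (prev[w] > bs) { bs = prev[w]; bw = w; }
    }
    if (bw < 0) stop("alignment band too narrow for these lengths");
    end_j = na + dlo + bw;
    score = bs;
  }

  // traceback
  std::vector<std::pair<int, int>> rev_ops; // (op, len) reversed
  int i = na, j = end_j;
  int matches = 0, block_len = 0, n_excl = 0;
  int t_end = end_j, t_start = 0;
  auto push_op = [&](int op) {
    if (!rev_ops.empty() && rev_ops.back().first == op) rev_ops.back().second++;
    else rev_ops.emplace_back(op, 1);
  };
  while (i > 0 || j > 0) {
    int w = j - i - dlo;
    uint8_t dir = (w >= 0 && w < W) ? tb[(size_t)i * W + w] : 255;
    if (dir == 4) break; // glocal origin on row 0
    if (dir == 255) stop("traceback left the band");
    if (dir == 0) {
      int ca = av[i - 1], cb = bv[j - 1];
      bool anyN = (ca == 4 || cb == 4);
      if (anyN) { ++n_excl; push_op(ca == cb ? 0 : 1); }
      else if (ca == cb) { ++matches; push_op(0); }
      else push_op(1);
      ++block_len; --i; --j;
    } else if (dir == 1) {
      push_op(3); ++block_len; --i;
    } else if (dir == 2) {
      push_op(2); ++block_len; --j;
    } else {
      stop("corrupt traceback");
    }
  }
  t_start = j;
  if (mode == 0) t_start = 0;

  IntegerMatrix ops((int)rev_ops.size(), 2);
  int r = (int)rev_ops.size();
  for (int q = 0; q < r; ++q) {
    ops(q, 0) = rev_ops[r - 1 - q].first;
    ops(q, 1) = rev_ops[r - 1 - q].second;
  }
  return List::create(_["matches"] = matches, _["block_len"] = block_len,
                      _["n_excluded"] = n_excl, _["t_start"] = t_start,
                      _["t_end"] = t_end, _["ops"] = ops, _["score"] = score);
}

// Shared k-mers that are unique within each of the two sequences.
// Returns an integer matrix with 0-based start positions (pos_a, pos_b),
// sorted by pos_a. k-mers containing N are skipped. k <= 31.
// [[Rcpp::export(name = ".cpp_shared_unique_anchors")]]
IntegerMatrix cpp_shared_unique_anchors(std::string a, std::string b, int k = 21) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  auto scan = [&](const std::string &s,
                  std::unordered_map<uint64_t, std::pair<int, int>> &m) {
    const int n = (int)s.size();
    if (n < k) return;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = nt_code(s[i]);
      if (c == 4) { valid = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        auto it = m.find(cur);
        if (it == m.end()) m.emplace(cur, std::make_pair(i - k + 1, 1));
        else it->second.second++;
      }
    }
  };
  std::unordered_map<uint64_t, std::pair<int, int>> ma, mb;
  ma.reserve(a.size() * 2); mb.reserve(b.size() * 2);
  scan(a, ma); scan(b, mb);
  std::vector<std::pair<int, int>> anchors;
  for (auto &kv : ma) {
    if (kv.second.second != 1) continue;
    auto it = mb.find(kv.first);
    if (it != mb.end() && it->second.second == 1)
      anchors.emplace_back(kv.second.first, it->second.first);
  }
  std::sort(anchors.begin(), anchors.end());
  IntegerMatrix out((int)anchors.size(), 2);
  for (int i = 0; i < (int)anchors.size(); ++i) {
    out(i, 0) = anchors[i].first;
    out(i, 1) = anchors[i].second;
  }
  return out;
}

// Longest strictly increasing subsequence; returns 1-based indices into y.
// [[Rcpp::export(name = ".cpp_lis")]]
IntegerVector cpp_lis(IntegerVector y) {
  const int n = y.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tail_val, tail_idx, parent(n, -1);
  for (int i = 0; i < n; ++i) {
    int v = y[i];
    int lo = (int)(std::lower_bound(tail_val.begin(), tail_val.end(), v) -
                   tail_val.begin());
    if (lo > 0) parent[i] = tail_idx[lo - 1];
    if (lo == (int)tail_val.size()) { tail_val.push_back(v); tail_idx.push_back(i); }
    else { tail_val[lo] = v; tail_idx[lo] = i; }
  }
  int L = (int)tail_val.size();
  IntegerVector out(L);
  int cur = tail_idx[L - 1];
  for (int p = L - 1; p >= 0; --p) { out[p] = cur + 1; cur = parent[cur]; }
  return out;
}

static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

// Minimizer sketch: hashes of window-minimum k-mers, masked to 52 bits so
// they round-trip exactly through R doubles. Sorted, deduplicated.
// [[Rcpp::export(name = ".cpp_minimizers")]]
NumericVector cpp_minimizers(std::string s, int k = 15, int w = 10) {
  const int n = (int)s.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (n < k) return NumericVector(0);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<uint64_t> hashes;
  uint64_t cur = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = nt_code(s[i]);
    if (c == 4) { valid = 0; cur = 0; hashes.push_back(UINT64_MAX); continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    ++valid;
    hashes.push_back(valid >= k ? mix64(cur) : UINT64_MAX);
  }
  // hashes[i] is hash of k-mer ending at i (start i-k+1)
  std::vector<uint64_t> mins;
  int nk = n; // positions with defined-or-not hash
  for (int start = k - 1; start < nk; start += 1) {
    // sliding window minimum over w consecutive k-mer hashes
    if (start + w - 1 >= nk && start != k - 1) break;
    int end = std::min(start + w - 1, nk - 1);
    uint64_t m = UINT64_MAX;
    for (int t = start; t <= end; ++t) m = std::min(m, hashes[t]);
    if (m != UINT64_MAX) mins.push_back(m);
    start += w - 1; // non-overlapping windows are a sufficient sketch here
  }
  std::sort(mins.begin(), mins.end());
  mins.erase(std::unique(mins.begin(), mins.end()), mins.end());
  NumericVector out((int)mins.size());
  const uint64_t m52 = (1ULL << 52) - 1;
  for (int i = 0; i < (int)mins.size(); ++i) out[i] = (double)(mins[i] & m52);
  return out;
}
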