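// Alignment kernels.
//
// cpp_align_banded: affine-gap global alignment restricted to a band around
// the diagonal traced by an anchor chain, followed by boundary trimming that
// keeps the longest contiguous alignment window whose error rate stays
// within eps. The window is clamped to the anchor-chain footprint so random
// flanking sequence (which carries no anchors) cannot inflate the call, and
// within the clamp the longest-window search uses the prefix-sum /
// prefix-maximum technique in O(n log n).
//
// cpp_edit_dist: exact Levenshtein distance with traceback, tie-broken
// toward the fewest gaps (diagonal preferred), returning the alignment
// length ell and err = E / ell.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
#include <cstdint>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static std::string rle_cigar(const std::vector<char> &ops, size_t lo, size_t hi) {
  std::string out;
  size_t t = lo;
  while (t < hi) {
    size_t u = t;
    while (u < hi && ops[u] == ops[t]) ++u;
    out += std::to_string(u - t);
    char c = ops[t];
    out.push_back(c == '=' || c == 'X' ? c : c); // M ops kept as =/X
    t = u;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_banded(std::string sa, std::string sb, IntegerMatrix chain,
                      int band_radius, double eps, int anchor_k = 10,
                      int match = 1, int mismatch = -1,
                      int gap_open = -2, int gap_ext = -1) {
  const int la = (int) sa.size(), lb = (int) sb.size();
  if (la == 0 || lb == 0 || chain.nrow() == 0)
    return List::create(_["score"] = 0);
  const int nc = chain.nrow();
  // per-row band center interpolated through the chain
  std::vector<int> center(la + 1);
  {
    int c0 = chain(0, 1) - chain(0, 0);
    int cN = chain(nc - 1, 1) - chain(nc - 1, 0);
    int ai = 0;
    for (int i = 0; i <= la; ++i) {
      int ci;
      if (i <= chain(0, 0)) ci = i + c0;
      else if (i >= chain(nc - 1, 0)) ci = i + cN;
      else {
        while (ai + 1 < nc && chain(ai + 1, 0) < i) ++ai;
        int i1 = chain(ai, 0), j1 = chain(ai, 1);
        int i2 = chain(std::min(ai + 1, nc - 1), 0), j2 = chain(std::min(ai + 1, nc - 1), 1);
        if (i2 <= i1) ci = j1 + (i - i1);
        else ci = j1 + (int) ((double) (j2 - j1) * (i - i1) / (i2 - i1));
      }
      center[i] = std::min(lb, std::max(0, ci));
    }
  }
  std::vector<int> jlo(la + 1), jhi(la + 1);
  for (int i = 0; i <= la; ++i) {
    int clo = center[i], chi = center[i];
    if (i > 0)  { clo = std::min(clo, center[i - 1]); chi = std::max(chi, center[i - 1]); }
    if (i < la) { clo = std::min(clo, center[i + 1]); chi = std::max(chi, center[i + 1]); }
    jlo[i] = std::max(0, clo - band_radius);
    jhi[i] = std::min(lb, chi + band_radius);
  }
  std::vector<size_t> off(la + 2, 0);
  for (int i = 0; i <= la; ++i) off[i + 1] = off[i] + (size_t) (jhi[i] - jlo[i] + 1);
  std::vector<uint8_t> tb(off[la + 1], 0);
  std::vector<int> Mp, Ep, Fp, Mc, Ec, Fc;
  int wmax = 0;
  for (int i = 0; i <= la; ++i) wmax = std::max(wmax, jhi[i] - jlo[i] + 1);
  Mp.assign(wmax + 1, NEG); Ep.assign(wmax + 1, NEG); Fp.assign(wmax + 1, NEG);
  Mc.assign(wmax + 1, NEG); Ec.assign(wmax + 1, NEG); Fc.assign(wmax + 1, NEG);

  // row 0: straight gap run from the corner (cost computable even when the
  // corner lies outside the window)
  for (int j = jlo[0]; j <= jhi[0]; ++j) {
    int w = j - jlo[0];
    if (j == 0) { Mp[w] = 0; Ep[w] = NEG; Fp[w] = NEG; }
    else { Mp[w] = NEG; Ep[w] = gap_open + (j - 1) * gap_ext; Fp[w] = NEG; }
    tb[off[0] + w] = (uint8_t) ((0) | (1 << 2) | (2 << 4) | ((j == 0 ? 0 : 1) << 6));
  }
  for (int i = 1; i <= la; ++i) {
    char ai = sa[i - 1];
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ec.begin(), Ec.end(), NEG);
    std::fill(Fc.begin(), Fc.end(), NEG);
    for (int j = jlo[i]; j <= jhi[i]; ++j) {
      int w = j - jlo[i];
      int wpd = (j - 1) - jlo[i - 1];
      int wpu = j - jlo[i - 1];
      bool okd = (j - 1 >= jlo[i - 1] && j - 1 <= jhi[i - 1]);
      bool oku = (j >= jlo[i - 1] && j <= jhi[i - 1]);
      int M = NEG; uint8_t mp = 0;
      if (j >= 1 && okd) {
        int base = Mp[wpd]; uint8_t lay = 0;
        if (Ep[wpd] > base) { base = Ep[wpd]; lay = 1; }
        if (Fp[wpd] > base) { base = Fp[wpd]; lay = 2; }
        if (base > NEG / 2) {
          int s = (ai == sb[j - 1] && ai != 'N') ? match : mismatch;
          M = base + s; mp = lay;
        }
      }
      int E = NEG; uint8_t ep = 1;
      if (j == 0) { E = NEG; }
      else if (j - 1 >= jlo[i]) {
        int wl = (j - 1) - jlo[i];
        int open_from = std::max(Mc[wl], Fc[wl]);
        uint8_t opl = (Mc[wl] >= Fc[wl]) ? 0 : 2;
        int ext = (Ec[wl] > NEG / 2) ? Ec[wl] + gap_ext : NEG;
        int opn = (open_from > NEG / 2) ? open_from + gap_open : NEG;
        if (opn >= ext) { E = opn; ep = opl; } else { E = ext; ep = 1; }
      }
      int F = NEG; uint8_t fp = 2;
      if (i >= 1 && oku) {
        int open_from = std::max(Mp[wpu], Ep[wpu]);
        uint8_t opl = (Mp[wpu] >= Ep[wpu]) ? 0 : 1;
        int ext = (Fp[wpu] > NEG / 2) ? Fp[wpu] + gap_ext : NEG;
        int opn = (open_from > NEG / 2) ? open_from + gap_open : NEG;
        if (opn >= ext) { F = opn; fp = opl; } else { F = ext; fp = 2; }
      } else if (j == 0) {
        F = gap_open + (i - 1) * gap_ext; fp = 2;
      }
      Mc[w] = M; Ec[w] = E; Fc[w] = F;
      int bl = 0, bs = M;
      if (E > bs) { bs = E; bl = 1; }
      if (F > bs) { bs = F; bl = 2; }
      tb[off[i] + w] = (uint8_t) ((mp & 3) | ((ep & 3) << 2) | ((fp & 3) << 4) | ((bl & 3) << 6));
    }
    std::swap(Mp, Mc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  // traceback start: (la, lb) when reachable, else the best cell of row la
  int ti = la, tj, tlayer;
  {
    int best = NEG, bj = jlo[la], bl = 0;
    for (int j = jlo[la]; j <= jhi[la]; ++j) {
      int w = j - jlo[la];
      int v = std::max(Mp[w], std::max(Ep[w], Fp[w]));
      int lay = (Mp[w] >= Ep[w] && Mp[w] >= Fp[w]) ? 0 : (Ep[w] >= Fp[w] ? 1 : 2);
      if (j == lb) { best = v; bj = j; bl = lay; break; }
      if (v > best) { best = v; bj = j; bl = lay; }
    }
    if (best <= NEG / 2) return List::create(_["score"] = 0);
    tj = bj; tlayer = bl;
  }
  std::vector<char> ops;
  std::vector<int> col_i, col_j; // (i, j) AFTER consuming each column, reversed
  {
    int i = ti, j = tj, layer = tlayer;
    while (i > 0 || j > 0) {
      if (i == 0) { ops.push_back('I'); col_i.push_back(i); col_j.push_back(j); --j; continue; }
      if (j == 0) { ops.push_back('D'); col_i.push_back(i); col_j.push_back(j); --i; continue; }
      uint8_t code = tb[off[i] + (j - jlo[i])];
      if (layer == 0) {
        ops.push_back((sa[i - 1] == sb[j - 1] && sa[i - 1] != 'N') ? '=' : 'X');
        col_i.push_back(i); col_j.push_back(j);
        layer = code & 3; --i; --j;
      } else if (layer == 1) {
        ops.push_back('I'); col_i.push_back(i); col_j.push_back(j);
        layer = (code >> 2) & 3; --j;
      } else {
        ops.push_back('D'); col_i.push_back(i); col_j.push_back(j);
        layer = (code >> 4) & 3; --i;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(col_i.begin(), col_i.end());
  std::reverse(col_j.begin(), col_j.end());
  const size_t n = ops.size();
  if (n == 0) return List::create(_["score"] = 0);

  // clamp window to the chain footprint (anchored homology only)
  int ci0 = chain(0, 0), ci1 = chain(nc - 1, 0) + anchor_k;
  int cj0 = chain(0, 1), cj1 = chain(nc - 1, 1) + anchor_k;
  size_t lo = 0, hi = n;
  while (lo < n && (col_i[lo] <= ci0 || col_j[lo] <= cj0)) ++lo;
  while (hi > lo && (col_i[hi - 1] > ci1 || col_j[hi - 1] > cj1)) --hi;
  if (lo > 0) --lo; // include the boundary column
  if (hi - lo < 1) { lo = 0; hi = n; }

  // longest contiguous window with mean edit cost <= eps inside [lo, hi)
  {
    const size_t m = hi - lo;
    std::vector<double> S(m + 1, 0.0);
    for (size_t t = 0; t < m; ++t)
      S[t + 1] = S[t] + ((ops[lo + t] == '=') ? -eps : 1.0 - eps);
    // longest (l, r) with S[r] - S[l] <= 0: smallest l with S[l] >= S[r];
    // prefix maxima are non-decreasing, and the first index where the
    // prefix max reaches S[r] attains it, so binary search returns l itself
    std::vector<double> pmax(m + 1);
    pmax[0] = S[0];
    for (size_t t = 1; t <= m; ++t) pmax[t] = std::max(pmax[t - 1], S[t]);
    size_t best_len = 0, best_l = 0, best_r = 0;
    for (size_t r = 1; r <= m; ++r) {
      size_t a = 0, b = r - 1;
      if (pmax[b] < S[r]) continue;
      while (a < b) { size_t mid = (a + b) / 2; if (pmax[mid] >= S[r]) b = mid; else a = mid + 1; }
      if (r - a > best_len) { best_len = r - a; best_l = a; best_r = r; }
    }
    if (best_len == 0) return List::create(_["score"] = 0);
    lo = lo + best_l; hi = lo + (best_r - best_l);
  }
  // drop leading/trailing gap columns, then grow through exact matches
  // beyond the chain clamp (pure-match stretches cannot be flank noise)
  while (lo < hi && (ops[lo] == 'I' || ops[lo] == 'D')) ++lo;
  while (hi > lo && (ops[hi - 1] == 'I' || ops[hi - 1] == 'D')) --hi;
  while (lo > 0 && ops[lo - 1] == '=') --lo;
  while (hi < n && ops[hi] == '=') ++hi;
  if (hi <= lo) return List::create(_["score"] = 0);

  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  for (size_t t = lo; t < hi; ++t) {
    switch (ops[t]) {
      case '=': ++nmatch; break;
      case 'X': ++nmis; break;
      case 'I': ++nins; break;
      default: ++ndel;
    }
  }
  int a0 = col_i[lo] - (ops[lo] != 'I' ? 1 : 0);
  int b0 = col_j[lo] - (ops[lo] != 'D' ? 1 : 0);
  int a1 = col_i[hi - 1], b1 = col_j[hi - 1];
  int E = nmis + nins + ndel;
  int ell = nmatch + nmis + nins + ndel;
  int score = nmatch * match + nmis * mismatch;
  // gap runs contribute open + ext*(len-1)
  {
    size_t t = lo;
    while (t < hi) {
      if (ops[t] == 'I' || ops[t] == 'D') {
        char c = ops[t]; size_t u = t;
        while (u < hi && ops[u] == c) ++u;
        score += gap_open + (int) (u - t - 1) * gap_ext;
        t = u;
      } else ++t;
    }
  }
  return List::create(
    _["score"] = score,
    _["a_start"] = a0, _["a_end"] = a1,
    _["b_start"] = b0, _["b_end"] = b1,
    _["cigar"] = rle_cigar(ops, lo, hi),
    _["nmatch"] = nmatch, _["nmis"] = nmis, _["nins"] = nins, _["ndel"] = ndel,
    _["E"] = E, _["ell"] = ell,
    _["err"] = (ell > 0) ? (double) E / ell : 0.0);
}

// Exact Levenshtein with traceback; ties prefer the diagonal (fewest gaps).
// [[Rcpp::export]]
List cpp_edit_dist(std::string sa, std::string sb) {
  const int n = (int) sa.size(), m = (int) sb.size();
  if (n == 0 || m == 0) {
    int E = std::max(n, m), ell = std::max(n, m);
    std::string cig;
    if (n > 0) cig = std::to_string(n) + "D";
    else if (m > 0) cig = std::to_string(m) + "I";
    return List::create(_["E"] = E, _["ell"] = ell,
                        _["err"] = ell > 0 ? (double) E / ell : 0.0,
                        _["cigar"] = cig);
  }
  if ((double) (n + 1) * (m + 1) > 4e8) stop("sequences too long for exact DP");
  std::vector<uint8_t> tb((size_t) (n + 1) * (m + 1));
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; tb[(size_t) i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (sa[i - 1] == sb[j - 1] ? 0 : 1);
      int del = prev[j] + 1, ins = cur[j - 1] + 1;
      int best = sub; uint8_t mv = 0;
      if (del < best) { best = del; mv = 1; }
      if (ins < best) { best = ins; mv = 2; }
      cur[j] = best; tb[(size_t) i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  int E = prev[m];
  std::vector<char> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t mv = tb[(size_t) i * (m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) { ops.push_back(sa[i - 1] == sb[j - 1] ? '=' : 'X'); --i; --j; }
    else if (i > 0 && (j == 0 || mv == 1)) { ops.push_back('D'); --i; }
    else { ops.push_back('I'); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  int ell = (int) ops.size();
  return List::create(_["E"] = E, _["ell"] = ell,
                      _["err"] = (double) E / ell,
                      _["cigar"] = rle_cigar(ops, 0, ops.size()));
}
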