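// Colinear k-mer matching, ordered Jaccard, anchor finding and chaining.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits_c(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// all valid k-mer (pos, code) of a string, no mask
static void encode_all(const std::string &s, int k,
                       std::vector<int> &pos, std::vector<uint64_t> &code) {
  const int n = (int) s.size();
  pos.clear(); code.clear();
  if (n < k) return;
  const uint64_t keep = (1ULL << (2 * k)) - 1;
  uint64_t cur = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits_c(s[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) b) & keep;
    if (++run >= k) { pos.push_back(i - k + 1); code.push_back(cur); }
  }
}

// Longest strictly-increasing chain over match pairs (i asc, j desc order,
// then LIS on j with strict increase).
static int lis_size(std::vector<std::pair<int,int> > &pairs) {
  std::sort(pairs.begin(), pairs.end(),
            [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
              if (a.first != b.first) return a.first < b.first;
              return a.second > b.second;
            });
  std::vector<int> tails;
  for (size_t t = 0; t < pairs.size(); ++t) {
    int j = pairs[t].second;
    auto it = std::lower_bound(tails.begin(), tails.end(), j);
    if (it == tails.end()) tails.push_back(j); else *it = j;
  }
  return (int) tails.size();
}

// Longest strictly-increasing chain over match pairs, returning the chain
// itself (positions in a and b).
static void lis_chain(std::vector<std::pair<int,int> > &pairs,
                      std::vector<std::pair<int,int> > &chain) {
  std::sort(pairs.begin(), pairs.end(),
            [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
              if (a.first != b.first) return a.first < b.first;
              return a.second > b.second;
            });
  const size_t m = pairs.size();
  std::vector<int> tails_j; std::vector<size_t> tails_id;
  std::vector<int> pred(m, -1);
  for (size_t t = 0; t < m; ++t) {
    int j = pairs[t].second;
    auto it = std::lower_bound(tails_j.begin(), tails_j.end(), j);
    size_t p = it - tails_j.begin();
    pred[t] = (p == 0) ? -1 : (int) tails_id[p - 1];
    if (it == tails_j.end()) { tails_j.push_back(j); tails_id.push_back(t); }
    else { *it = j; tails_id[p] = t; }
  }
  chain.clear();
  if (tails_id.empty()) return;
  for (int t = (int) tails_id.back(); t != -1; t = pred[t])
    chain.push_back(pairs[t]);
  std::reverse(chain.begin(), chain.end());
}

// Maximum colinear k-mer matching size, set union size, and ordered Jaccard.
// Every occurrence pair of a shared k-mer is a matching candidate (capped at
// max_occ occurrences per k-mer per string). When win > 0, additionally
// reports the best ordered Jaccard over windows of `win` bases slid along
// the maximum colinear chain (the filtering problem asks for *any* pair of
// substrings of at least the minimum SD size reaching tau, so a locally
// dense sub-window of a long candidate qualifies it).
// [[Rcpp::export]]
List cpp_ordered_jaccard(std::string sa, std::string sb, int k,
                         int max_occ = 1000, int win = 0) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  std::vector<int> pa, pb; std::vector<uint64_t> ca, cb;
  encode_all(sa, k, pa, ca);
  encode_all(sb, k, pb, cb);
  std::unordered_map<uint64_t, std::vector<int> > mb;
  for (size_t t = 0; t < pb.size(); ++t) {
    std::vector<int> &v = mb[cb[t]];
    if ((int) v.size() < max_occ) v.push_back(pb[t]);
  }
  std::vector<std::pair<int,int> > pairs;
  {
    std::unordered_map<uint64_t, int> seen_a;
    for (size_t t = 0; t < pa.size(); ++t) {
      auto it = mb.find(ca[t]);
      if (it == mb.end()) continue;
      int &cnt = seen_a[ca[t]];
      if (cnt >= max_occ) continue;
      ++cnt;
      for (int j : it->second) pairs.push_back(std::make_pair(pa[t], j));
    }
  }
  std::vector<std::pair<int,int> > chain;
  int shared = 0;
  if (!pairs.empty()) { lis_chain(pairs, chain); shared = (int) chain.size(); }
  std::unordered_set<uint64_t> uni(ca.begin(), ca.end());
  uni.insert(cb.begin(), cb.end());
  int u = (int) uni.size();
  double jac = (u == 0) ? 0.0 : (double) shared / (double) u;
  double best_win = jac;
  if (win > 0 && !chain.empty()) {
    const int m = (int) chain.size();
    for (int l = 0, r = 0; l < m; ++l) {
      if (r < l) r = l;
      while (r + 1 < m && chain[r + 1].first - chain[l].first < win) ++r;
      int sh = r - l + 1;
      int span_a = chain[r].first - chain[l].first + k;
      int span_b = chain[r].second - chain[l].second + k;
      int wa = std::max(span_a, std::min(win, (int) sa.size()));
      int wb = std::max(span_b, wa);
      // window union approximated from window k-mer counts
      int uw = std::max(1, wa - k + 1 + wb - k + 1 - sh);
      double jw = (double) sh / (double) uw;
      if (jw > best_win) best_win = jw;
    }
  }
  return List::create(_["shared"] = shared, _["union_size"] = u,
                      _["jaccard"] = jac,
                      _["window_jaccard"] = best_win,
                      _["n_kmers_a"] = (int) pa.size(),
                      _["n_kmers_b"] = (int) pb.size());
}

// Shared k-mer anchors between two strings: matrix with 0-based columns (i, j).
// [[Rcpp::export]]
IntegerMatrix cpp_anchors(std::string sa, std::string sb, int k, int max_occ = 100) {
  std::vector<int> pa, pb; std::vector<uint64_t> ca, cb;
  encode_all(sa, k, pa, ca);
  encode_all(sb, k, pb, cb);
  std::unordered_map<uint64_t, std::vector<int> > mb;
  for (size_t t = 0; t < pb.size(); ++t) {
    std::vector<int> &v = mb[cb[t]];
    if ((int) v.size() < max_occ) v.push_back(pb[t]);
  }
  std::vector<std::pair<int,int> > pairs;
  for (size_t t = 0; t < pa.size(); ++t) {
    auto it = mb.find(ca[t]);
    if (it == mb.end()) continue;
    for (int j : it->second) {
      pairs.push_back(std::make_pair(pa[t], j));
      if (pairs.size() > 4000000) stop("anchor set too large; raise k or lower max_occ");
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int) pairs.size(), 2);
  for (size_t t = 0; t < pairs.size(); ++t) {
    out(t, 0) = pairs[t].first; out(t, 1) = pairs[t].second;
  }
  return out;
}

// Repeatedly extract the best strictly-colinear anchor chain (unit-weight LIS
// with predecessor tracking), split it where the gap on either axis exceeds
// gap_split, drop pieces with fewer than min_anchors anchors, then remove all
// anchors overlapping the extracted chain's bounding boxes and iterate.
// Returns a list of (n x 2) anchor matrices, best chain first.
// [[Rcpp::export]]
List cpp_chain_anchors(IntegerMatrix anchors, int k, int gap_split,
                       int min_anchors, int max_chains = 16) {
  int m = anchors.nrow();
  std::vector<std::pair<int,int> > P(m);
  for (int t = 0; t < m; ++t) P[t] = std::make_pair(anchors(t, 0), anchors(t, 1));
  std::sort(P.begin(), P.end(),
            [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
              if (a.first != b.first) return a.first < b.first;
              return a.second > b.second;
            });
  std::vector<char> alive(m, 1);
  List chains;
  for (int round = 0; round < max_chains; ++round) {
    // LIS with predecessors over alive anchors
    std::vector<int> idx; idx.reserve(m);
    for (int t = 0; t < m; ++t) if (alive[t]) idx.push_back(t);
    if ((int) idx.size() < min_anchors) break;
    std::vector<int> tails_j, tails_id, pred(idx.size(), -1);
    for (size_t u = 0; u < idx.size(); ++u) {
      int j = P[idx[u]].second;
      auto it = std::lower_bound(tails_j.begin(), tails_j.end(), j);
      size_t ppos = it - tails_j.begin();
      pred[u] = (ppos == 0) ? -1 : tails_id[ppos - 1];
      if (it == tails_j.end()) { tails_j.push_back(j); tails_id.push_back((int) u); }
      else { *it = j; tails_id[ppos] = (int) u; }
    }
    if ((int) tails_j.size() < min_anchors) break;
    // walk back the best chain
    std::vector<int> chain_u;
    for (int u = tails_id.back(); u != -1; u = pred[u]) chain_u.push_back(u);
    std::reverse(chain_u.begin(), chain_u.end());
    // split at large gaps
    std::vector<std::vector<int> > pieces;
    pieces.push_back(std::vector<int>());
    for (size_t t = 0; t < chain_u.size(); ++t) {
      if (!pieces.back().empty()) {
        int pu = pieces.back().back(), cu = (int) t;
        int di = P[idx[chain_u[cu]]].first  - P[idx[pu]].first;
        int dj = P[idx[chain_u[cu]]].second - P[idx[pu]].second;
        if (di > gap_split || dj > gap_split) pieces.push_back(std::vector<int>());
      }
      pieces.back().push_back(chain_u[t]);
    }
    bool emitted = false;
    int min_i = INT_MAX, max_i = -1, min_j = INT_MAX, max_j = -1;
    for (auto &pc : pieces) {
      int a0 = P[idx[pc.front()]].first, a1 = P[idx[pc.back()]].first + k;
      int b0 = P[idx[pc.front()]].second, b1 = P[idx[pc.back()]].second + k;
      min_i = std::min(min_i, a0); max_i = std::max(max_i, a1);
      min_j = std::min(min_j, b0); max_j = std::max(max_j, b1);
      if ((int) pc.size() < min_anchors) continue;
      IntegerMatrix cm((int) pc.size(), 2);
      for (size_t t = 0; t < pc.size(); ++t) {
        cm(t, 0) = P[idx[pc[t]]].first;
        cm(t, 1) = P[idx[pc[t]]].second;
      }
      chains.push_back(cm);
      emitted = true;
    }
    // remove anchors overlapping the extracted chain's footprint
    for (int t = 0; t < m; ++t) {
      if (!alive[t]) continue;
      int i = P[t].first, j = P[t].second;
      if ((i + k > min_i && i < max_i) || (j + k > min_j && j < max_j)) alive[t] = 0;
    }
    if (!emitted && max_i < 0) break;
  }
  return chains;
}
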