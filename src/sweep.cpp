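// Plane-sweep detection of putative segmental duplications.
//
// The sweep walks the query fingerprint left to right. At each fingerprint
// position x it pulls the sorted occurrence list K of that k-mer from the
// index and reconciles K against the live candidate list L: each hit y either
// extends a live candidate whose frontier is within delta on both axes, is
// subsumed by a candidate that already covers it, or starts a new candidate.
// A candidate whose x-frontier falls more than max_gap behind the sweep line
// is retired and emitted if it accumulated at least min_shared colinear
// matches; the ordered-Jaccard acceptance test is applied afterwards by the
// caller on the exact sequences.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <list>
#include <cstdint>
using namespace Rcpp;

struct Live {
  int bx, by;   // first matched k-mer start on each axis
  int lx, ly;   // frontier: last matched k-mer start on each axis
  int shared;   // colinear matched k-mer count
};

// [[Rcpp::export]]
DataFrame cpp_plane_sweep(IntegerVector qpos, NumericVector qcode,
                          IntegerVector ipos, NumericVector icode,
                          int k, int delta, int max_gap,
                          int max_freq, bool self, int min_shared) {
  const int nq = qpos.size(), ni = ipos.size();
  // index hash: code -> occurrence list (ipos assumed sorted ascending)
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve((size_t) ni * 2 + 16);
  for (int i = 0; i < ni; ++i) idx[(uint64_t) icode[i]].push_back(ipos[i]);
  int dropped_codes = 0;
  for (auto it = idx.begin(); it != idx.end();) {
    if ((int) it->second.size() > max_freq) { it = idx.erase(it); ++dropped_codes; }
    else ++it;
  }

  std::list<Live> L; // kept sorted by by (interval_b start)
  std::vector<int> obx, oex, oby, oey, osh;
  auto retire = [&](const Live &e) {
    if (e.shared >= min_shared) {
      obx.push_back(e.bx); oex.push_back(e.lx + k);
      oby.push_back(e.by); oey.push_back(e.ly + k);
      osh.push_back(e.shared);
    }
  };

  for (int qi = 0; qi < nq; ++qi) {
    const int x = qpos[qi];
    // retire stale candidates
    for (auto it = L.begin(); it != L.end();) {
      if (x - it->lx > max_gap) { retire(*it); it = L.erase(it); }
      else ++it;
    }
    auto hit = idx.find((uint64_t) qcode[qi]);
    if (hit == idx.end()) continue;
    const std::vector<int> &K = hit->second;
    for (size_t j = 0; j < K.size(); ++j) {
      const int y = K[j];
      if (self && y <= x) continue;
      // scan L (sorted by by): first eligible frontier wins
      bool done = false;
      auto ins = L.end();
      for (auto it = L.begin(); it != L.end(); ++it) {
        if (it->by > y && ins == L.end()) ins = it;
        int dy = y - it->ly;
        if (dy > 0 && dy <= delta && x >= it->lx && x - it->lx <= delta + k) {
          it->lx = x; it->ly = y; it->shared++;
          done = true; break;
        }
        if (y >= it->by && y <= it->ly && x >= it->bx && x <= it->lx + delta) {
          done = true; break; // subsumed
        }
      }
      if (!done) L.insert(ins, Live{x, y, x, y, 1});
    }
  }
  for (auto &e : L) retire(e);

  DataFrame out = DataFrame::create(
    _["bx"] = obx, _["ex"] = oex, _["by"] = oby, _["ey"] = oey,
    _["shared"] = osh);
  out.attr("dropped_codes") = dropped_codes;
  return out;
}
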