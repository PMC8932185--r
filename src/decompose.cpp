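// Elementary-SD decomposition by k-mer chaining over the merged SD regions
// of one cluster.
//
// All sequences of the cluster are laid out left to right and scanned with a
// sweep line over a full (non-winnowed) k-mer index. Live putative elementary
// SDs each track several copies (one per duplicated region). A hit set H (all
// occurrences of the current k-mer) advances an element when its locations
// chain within d_g of the copies' frontiers. A copy-count change (a region
// joining or leaving the mosaic) closes the element at that boundary and
// opens a new one; joins must be confirmed by a second chained hit so a
// chance k-mer collision cannot split an element. At closure all member
// intervals of length >= mu are emitted as one elementary-SD set.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <list>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Copy {
  int start, last;       // global k-mer start positions (member = [start, last + k))
  int last_sweep;        // sweep position of last append
};

struct Pending {
  int start, last;       // provisional new copy
  int n_appends;
  std::vector<int> snap; // established copies' lasts when the join appeared
};

struct Elem {
  std::vector<Copy> copies;
  std::vector<Pending> pend;
  int last_append_sweep;
  long id;
};

static inline int b2b(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

} // namespace

// region_seqs: cluster region sequences (already oriented). Returns a list of
// sets; each set is an IntegerMatrix with columns (region, start, end),
// 0-based half-open coordinates local to the region. Members shorter than mu
// are dropped; sets with fewer than two surviving members are dropped.
// [[Rcpp::export]]
List cpp_decompose(CharacterVector region_seqs, int k, int dg, int mu,
                   int max_occ = 2000) {
  const int nr = region_seqs.size();
  std::vector<std::string> seqs(nr);
  std::vector<long> off(nr + 1, 0);
  for (int r = 0; r < nr; ++r) {
    seqs[r] = as<std::string>(region_seqs[r]);
    off[r + 1] = off[r] + (long) seqs[r].size();
  }
  const long total = off[nr];
  auto region_of = [&](long g) {
    int lo = 0, hi = nr - 1;
    while (lo < hi) { int mid = (lo + hi + 1) / 2; if (off[mid] <= g) lo = mid; else hi = mid - 1; }
    return lo;
  };

  // full k-mer index over all regions (global positions)
  std::vector<long> kpos; std::vector<uint64_t> kcode;
  {
    const uint64_t keep = (1ULL << (2 * k)) - 1;
    for (int r = 0; r < nr; ++r) {
      const std::string &s = seqs[r];
      uint64_t cur = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = b2b(s[i]);
        if (b < 0) { run = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint64_t) b) & keep;
        if (++run >= k) { kpos.push_back(off[r] + (long) i - k + 1); kcode.push_back(cur); }
      }
    }
  }
  std::unordered_map<uint64_t, std::vector<long> > idx;
  idx.reserve(kpos.size() * 2 + 16);
  for (size_t t = 0; t < kpos.size(); ++t) idx[kcode[t]].push_back(kpos[t]);
  for (auto it = idx.begin(); it != idx.end();) {
    if ((int) it->second.size() > max_occ || it->second.size() < 2) it = idx.erase(it);
    else ++it;
  }

  std::vector<char> covered(total, 0);
  std::list<Elem> L;
  long next_id = 0;
  List out;
  std::vector<IntegerMatrix> sets;

  auto emit = [&](Elem &e) {
    int keep = 0;
    for (auto &c : e.copies) if (c.last + k - c.start >= mu) ++keep;
    // mark everything processed either way
    for (auto &c : e.copies)
      for (long g = c.start; g < (long) c.last + k && g < total; ++g) covered[g] = 1;
    if (keep < 2) return;
    IntegerMatrix m(keep, 3);
    int row = 0;
    for (auto &c : e.copies) {
      if (c.last + k - c.start < mu) continue;
      int r = region_of(c.start);
      m(row, 0) = r;
      m(row, 1) = (int) (c.start - off[r]);
      m(row, 2) = (int) std::min((long) c.last + k - off[r], (long) seqs[r].size());
      ++row;
    }
    sets.push_back(m);
  };

  for (size_t t = 0; t < kpos.size(); ++t) {
    const long p = kpos[t];
    // retire stale elements
    for (auto it = L.begin(); it != L.end();) {
      if (p - it->last_append_sweep > dg) { emit(*it); it = L.erase(it); }
      else {
        // expire stale pendings
        auto &pd = it->pend;
        pd.erase(std::remove_if(pd.begin(), pd.end(),
                                [&](const Pending &q) { return p - (long) q.last > dg; }),
                 pd.end());
        ++it;
      }
    }
    if (covered[p]) continue;
    // skip positions already inside a live copy
    {
      bool inside = false;
      for (auto &e : L) {
        for (auto &c : e.copies)
          if (p >= c.start && p <= c.last) { inside = true; break; }
        if (inside) break;
      }
      if (inside) continue;
    }
    auto hit = idx.find(kcode[t]);
    if (hit == idx.end()) continue;
    std::vector<long> H;
    for (long h : hit->second) if (!covered[h]) H.push_back(h);
    if ((int) H.size() < 2) continue;

    // match H against live elements: per copy, nearest unconsumed hit in the
    // same region with 0 < h - last <= dg
    Elem *best = nullptr; int best_matched = 0;
    std::vector<int> best_assign; // per copy: index into H or -1
    for (auto &e : L) {
      std::vector<int> assign(e.copies.size(), -1);
      std::vector<char> used(H.size(), 0);
      int nm = 0;
      for (size_t ci = 0; ci < e.copies.size(); ++ci) {
        const Copy &c = e.copies[ci];
        int rc = region_of(c.start);
        int pick = -1; long bestd = (long) dg + 1;
        for (size_t hi2 = 0; hi2 < H.size(); ++hi2) {
          if (used[hi2]) continue;
          long d = H[hi2] - (long) c.last;
          if (d <= 0 || d > dg) continue;
          if (region_of(H[hi2]) != rc) continue;
          if (d < bestd) { bestd = d; pick = (int) hi2; }
        }
        if (pick >= 0) { used[pick] = 1; assign[ci] = pick; ++nm; }
      }
      if (nm > best_matched) { best_matched = nm; best = &e; best_assign = assign; }
    }

    if (!best || best_matched == 0) {
      Elem e; e.id = next_id++;
      for (long h : H) e.copies.push_back(Copy{(int) h, (int) h, (int) p});
      e.last_append_sweep = (int) p;
      L.push_back(std::move(e));
      continue;
    }

    Elem &e = *best;
    std::vector<char> used(H.size(), 0);
    for (size_t ci = 0; ci < e.copies.size(); ++ci)
      if (best_assign[ci] >= 0) used[best_assign[ci]] = 1;

    // copy-loss check: unmatched copy stale beyond dg => split
    bool loss = false;
    for (size_t ci = 0; ci < e.copies.size(); ++ci) {
      if (best_assign[ci] < 0 && p - (long) e.copies[ci].last_sweep > dg) { loss = true; break; }
    }
    if (loss) {
      Elem e2; e2.id = next_id++;
      for (size_t ci = 0; ci < e.copies.size(); ++ci) {
        if (best_assign[ci] < 0) continue;
        long h = H[best_assign[ci]];
        e2.copies.push_back(Copy{(int) h, (int) h, (int) p});
      }
      e2.last_append_sweep = (int) p;
      emit(e);
      // replace e in-place
      e = std::move(e2);
      continue;
    }

    // append matched copies
    for (size_t ci = 0; ci < e.copies.size(); ++ci) {
      if (best_assign[ci] < 0) continue;
      e.copies[ci].last = (int) H[best_assign[ci]];
      e.copies[ci].last_sweep = (int) p;
    }
    e.last_append_sweep = (int) p;

    // extra hits: provisional joining copies, confirmed on a second chained hit
    bool committed = false;
    for (size_t hi2 = 0; hi2 < H.size() && !committed; ++hi2) {
      if (used[hi2]) continue;
      long h = H[hi2];
      bool matched_pending = false;
      for (auto &q : e.pend) {
        long d = h - (long) q.last;
        if (d > 0 && d <= dg && region_of(h) == region_of(q.start)) {
          q.last = (int) h; q.n_appends++;
          matched_pending = true;
          // confirm a join only once the provisional copy has chained over
          // at least k bases: a chance repeated k-mer (or (k+1)-mer) then
          // cannot masquerade as a new elementary-SD copy
          if (q.last - q.start >= k) {
            // commit: close e at the join point, reopen with all copies
            Elem closed; closed.id = e.id;
            closed.copies = e.copies;
            for (size_t ci = 0; ci < closed.copies.size() && ci < q.snap.size(); ++ci)
              closed.copies[ci].last = q.snap[ci];
            emit(closed);
            Elem e2; e2.id = next_id++;
            for (size_t ci = 0; ci < e.copies.size(); ++ci) {
              int st = (ci < q.snap.size()) ? q.snap[ci] : e.copies[ci].start;
              e2.copies.push_back(Copy{st, e.copies[ci].last, e.copies[ci].last_sweep});
            }
            e2.copies.push_back(Copy{q.start, q.last, (int) p});
            e2.last_append_sweep = (int) p;
            e = std::move(e2);
            committed = true;
          }
          break;
        }
      }
      if (!matched_pending && !committed) {
        Pending q; q.start = (int) h; q.last = (int) h; q.n_appends = 0;
        for (auto &c : e.copies) q.snap.push_back(c.last);
        e.pend.push_back(q);
      }
    }
  }
  for (auto &e : L) emit(e);

  List res(sets.size());
  for (size_t t = 0; t < sets.size(); ++t) res[t] = sets[t];
  return res;
}
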