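// k-mer encoding and winnowing primitives.
//
// k-mers are packed 2 bits per residue with A<C<G<T, so integer order on the
// code coincides with lexicographic order on the residues. Codes are returned
// as doubles (exact for k <= 26). Windows touching a masked residue or an N
// produce no k-mer.

#include <Rcpp.h>
#include <deque>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or anything else: invalid
  }
}

// Encode all valid k-mers of one sequence.
// mask: optional logical vector (length 0 => nothing masked besides non-ACGT).
// Returns list(pos = 0-based start positions, code = packed codes).
// [[Rcpp::export]]
List cpp_encode_kmers(std::string seq, LogicalVector mask, int k) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  const int n = (int) seq.size();
  std::vector<int> pos;
  std::vector<double> code;
  if (n < k) return List::create(_["pos"] = pos, _["code"] = code);
  const bool has_mask = mask.size() > 0;
  if (has_mask && (int) mask.size() != n) stop("mask length != sequence length");

  const uint64_t keep = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0; // number of consecutive valid residues ending here
  for (int i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    bool bad = (b < 0) || (has_mask && mask[i]);
    if (bad) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) b) & keep;
    if (++run >= k) {
      pos.push_back(i - k + 1);
      code.push_back((double) cur);
    }
  }
  return List::create(_["pos"] = pos, _["code"] = code);
}

// Canonical winnowing order: a fixed bit-mix (splitmix64 finalizer) of the
// packed code. A pseudo-random order keeps the fingerprint density at the
// expected 2/(w+1); ordering k-mers by raw lexicographic rank inflates it
// by roughly 10% because overlapping low-rank k-mers correlate.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_order_key(NumericVector code) {
  NumericVector out(code.size());
  for (int i = 0; i < code.size(); ++i)
    out[i] = (double) (mix64((uint64_t) code[i]) >> 11); // 53-bit, exact double
  return out;
}

// Winnowing fingerprint: for every window of w consecutive k-mers take the
// one smallest in the canonical order, rightmost on ties (ties arise exactly
// for repeated k-mers); streaming monotone deque, O(w) working space.
// Returns the 0-based *indices into the input vectors* of selected k-mers
// (sorted, unique). Fewer than w k-mers => a single window over all of them.
// [[Rcpp::export]]
IntegerVector cpp_winnow(NumericVector code, int w) {
  const int m = code.size();
  if (w < 1) stop("w must be >= 1");
  std::vector<int> sel;
  if (m == 0) return IntegerVector(0);
  std::vector<uint64_t> key(m);
  for (int i = 0; i < m; ++i) key[i] = mix64((uint64_t) code[i]);
  if (m <= w) {
    // single window: pick min, rightmost tie
    int best = 0;
    for (int i = 1; i < m; ++i) if (key[i] <= key[best]) best = i;
    return IntegerVector::create(best);
  }
  std::deque<int> dq; // indices, keys strictly increasing front->back
  std::vector<char> taken(m, 0);
  for (int i = 0; i < m; ++i) {
    // rightmost tie-break: evict <= from the back
    while (!dq.empty() && key[dq.back()] >= key[i]) dq.pop_back();
    dq.push_back(i);
    while (dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1) {
      int j = dq.front();
      if (!taken[j]) { taken[j] = 1; sel.push_back(j); }
    }
  }
  return wrap(sel); // built in increasing order by construction
}

// Count fingerprint positions falling in [lo, hi) for each query interval.
// pos must be sorted ascending.
// [[Rcpp::export]]
IntegerVector cpp_count_in_range(IntegerVector pos, IntegerVector lo, IntegerVector hi) {
  int nq = lo.size();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    IntegerVector::iterator a = std::lower_bound(pos.begin(), pos.end(), lo[q]);
    IntegerVector::iterator b = std::lower_bound(pos.begin(), pos.end(), hi[q]);
    out[q] = (int) (b - a);
  }
  return out;
}
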