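---
title: "Detecting and decomposing segmental duplications: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and decomposing segmental duplications: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsweep)
```

## The problem

Segmental duplications (SDs) are genomic segments of at least 1 Kbp present
in two or more copies. Because copies diverge independently after the
duplication event, old SDs can differ by up to 25% — far beyond what
standard aligners tolerate — while a full self-alignment of a genome is
quadratic and infeasible. `dupsweep` finds SD candidates in near-linear
time with a k-mer filter, validates them by alignment, and then decomposes
the resulting SD set into *elementary SDs* (the minimal building blocks
from which SD mosaics are assembled) and *core duplicons* (the minimal
subset of elementary SDs touching every SD).

An SD at error threshold $\varepsilon$ is a pair of sequences $(s, s')$
with

1. edit error $err(s,s') = \mathcal{E}(s,s')/\ell \le \varepsilon$, where
   $\mathcal{E}$ is the Levenshtein distance and $\ell$ the optimal
   alignment length,
2. $\ell \ge 1000$, and
3. overlap between the two intervals of at most $\varepsilon \cdot n$
   bases, $n$ being the smaller span.

All three criteria are enforced on every emitted record
(`validate_sd()`), and the test suite re-verifies them from raw sequence.

## The two-component error model

Divergence between paralogs is modelled as a sum of two independent
processes ($\varepsilon = \varepsilon_P + \varepsilon_B$):

* **PSVs** (paralogous sequence variants): point mutations at rate
  $\varepsilon_P \le 0.15$, assumed Poisson. A k-mer survives in both
  copies with probability $e^{-k\varepsilon_P}$.
* **Block edits**: clustered insertions/deletions contributing the
  remaining $\varepsilon_B$ (0.10 at the 25% operating point), with a
  per-position event probability of roughly 0.5%.

For paralogs under this model the expected Jaccard index of their k-mer
sets is bounded below by

$$\tau = \frac{1-\varepsilon_B}{1+\varepsilon_B}\cdot
         \frac{1}{2e^{k\varepsilon_P}-1},$$

which for the defaults ($k = 14$, $\varepsilon_P = 0.15$,
$\varepsilon_B = 0.10$) gives $\tau \approx 0.0534$
(`tau_lower_bound(14, 0.15, 0.10)`). $\tau$ is the acceptance threshold of
the candidate search.

## Ordered Jaccard and the plane sweep

Classical Jaccard allows a k-mer anywhere in $s$ to match a k-mer anywhere
in $s'$, including *cross-over* matches no alignment could realize. The
**ordered Jaccard index** replaces the intersection with the size of a
maximum *colinear* matching $s \circledast s'$ (no two matched index pairs
cross), computed here as a longest-increasing-subsequence chain over all
occurrence pairs:

$$\hat{\mathcal J}(s, s') = \frac{s \circledast s'}
  {|\mathbf K(s) \cup \mathbf K(s')|}.$$

Under the model's assumptions (no repeated k-mers, shared k-mers shared
since the copy event) $\hat{\mathcal J}$ equals the classical Jaccard
index, a property the suite verifies exactly on simulated instances.

The search works as follows:

1. **Winnowed index.** Every chromosome is fingerprinted with minimizers:
   in each window of $w = 16$ consecutive k-mers ($k = 14$) the minimal
   k-mer under a fixed pseudo-random canonical order is kept (rightmost on
   ties), computed in one streaming pass with a monotone deque. Expected
   density is $2/(w+1)$; the suite checks the realized density on a
   megabase of random sequence to within 5%. We deliberately rank k-mers
   by a bit-mixed value of their 2-bit code rather than raw lexicographic
   rank: lexicographic minimizers on a 4-letter alphabet are roughly 10%
   denser than $2/(w+1)$ because overlapping low-rank k-mers correlate,
   and the pseudo-random order restores the density the complexity
   analysis assumes. Any fixed order gives identical matching semantics.
   Masked residues (lowercase in the input FASTA, plus `N`) produce no
   k-mers but keep their coordinates, so all output refers to the original
   assembly. k-mers occurring more than `max_freq = 1000` times are
   dropped as unmaskable repeats.
2. **Plane sweep.** The sweep line visits every valid k-mer position
   $x$ of the genome left to right and pulls the sorted occurrence list of
   that k-mer from the winnowed index. Each occurrence $y > x$ either
   extends a live candidate whose frontier is within $\Delta = 250$ bases
   on both axes, is subsumed by a candidate that already covers it, or
   starts a new candidate. A candidate whose frontier falls more than 250
   bases (the maximum gap of the smallest admissible SD) behind the sweep
   is retired. Sweeping all positions while indexing only the fingerprint
   keeps the sweep linear in the genome and the index small; it also makes
   a match require selection in only one of the two copies, which is what
   preserves sensitivity at 25% divergence where minimizer selection
   decorrelates between copies.
3. **Promotion.** A retired candidate is promoted when the ordered Jaccard
   of its spans — recomputed exactly from the sequences on full k-mer sets
   — reaches $\tau$ either globally or within the best window of
   $1000(1-\varepsilon)$ bases along its colinear chain (the filtering
   problem asks for *any* substring pair of admissible size reaching
   $\tau$), and when it satisfies the overlap rule. The promotion span
   floor is kept at 100 bases so that $\Delta$-fragmented pieces of small,
   highly diverged SDs survive to the merge step; the 1 Kbp length floor
   is enforced after alignment, where $\ell$ is actually known.
4. **Merge.** Nearby colinear candidates (each axis within the 5 Kbp
   extension radius) are merged when their united spans still pass
   $\tau$; contained candidates are absorbed. The operation is idempotent.

Inverted duplications are found by running the same sweep against a second
index built on the reverse complement of each chromosome; hits map back to
forward coordinates with strand `-`.

## Chaining and alignment

Each promoted candidate, extended by 5 Kbp on both flanks, is refined in
two tiers: tier 1 chains $k = 14$ anchors to split the region pair into
alignable sub-pairs; tier 2 re-anchors each sub-pair at $k = 10$ and
extracts maximum colinear chains by an $O(n\log n)$ LIS sweep. Chains are
split where the gap on either axis exceeds 600 bases — wider than any
single block edit the simulator can emit (block lengths are capped at 5%
of the SD, at most 500 bases), but too narrow for sparse chance anchors to
chain two distinct nearby duplications into one chimeric alignment. Chains
anchoring fewer than 200 bases are dropped; this is a guard against chance
chains only (a true 1 Kbp SD at 25% divergence still anchors ~450 bases).

When the two extended regions overlap on the genome (near-tandem
duplications), anchors on the genomic self-identity diagonal are excluded:
a valid SD's paralogs may overlap by at most $\varepsilon n$, so that
diagonal can never be part of a call, yet it would otherwise dominate
chaining.

Gaps between anchors are closed by banded affine dynamic programming
(match +1, mismatch −1, gap open −2, gap extend −1; band half-width
$2\Delta = 500$ following the chain diagonal, widened locally where the
diagonal jumps). Boundaries are then trimmed to the **longest contiguous
alignment window whose error rate stays within $\varepsilon$** — the
direct operationalization of criterion 1+2, which keeps tails beyond block
indels that a max-score trim would cut — clamped to the anchor-chain
footprint so that anchorless random flank cannot inflate the call, and
finally grown outward through exact-match columns only. `err`, $\ell$ and
the CIGAR are computed from the trimmed alignment; banded alignment can
overestimate the true edit distance slightly, never underestimate it, and
the suite checks agreement with an exact full-DP oracle.

## Decomposition into elementary SDs

Validated SDs are clustered by paralog-interval overlap (union-find);
each cluster's merged regions are decomposed independently, so results do
not depend on processing order. Within a cluster a *full* (non-winnowed)
$k = 10$ index is swept left to right. Live putative elementary SDs track
one frontier per copy; a hit set chains onto an element when each location
lies within $d_g = 50$ bases of the corresponding copy's frontier. A
change in the number of co-extending copies closes the element at that
boundary and opens a new one, which is what makes elementary-SD boundaries
land at SD boundaries and their paralog "images" (within $d_g$). Two
stabilizers matter in practice:

* a *joining* copy is provisional until it has chained over at least $k$
  bases, so a chance repeated k-mer cannot split an element;
* a *leaving* copy enjoys a $d_g$ grace window, so a PSV that wipes out
  $k$ consecutive k-mers on one copy does not end an element.

At closure all member intervals of at least $\mu = 100$ bases are emitted
as one elementary-SD set (singleton sets are dropped; members on
minus-strand paralogs are tracked in reverse-complement space and reported
with strand). $d_g = 50$ is large enough to absorb PSVs and small gaps
while covering elementary SDs of 100 bp and larger.

Core duplicons are selected by the classical greedy set-cover
approximation over "SD is covered by set" incidence (overlap by any base
of either paralog), with deterministic tie-breaking (coverage gain, then
total span, then set id). Composition distances between annotated regions
are $d = 1 - J$ over their elementary-set id sets, with
$d(\emptyset,\emptyset) = 0$ and $d(\emptyset, B) = 1$; trees use
neighbor-joining (`ape::nj`) and are exported as newick.

## The simulator

`simulate_genome()` generates the study conditions: an i.i.d. uniform
background, disjoint source segments of 1–10 Kbp, and copies spliced in at
loci outside every source. Each copy is mutated by:

* **block edits first**: insert/delete (fair coin) blocks with geometric
  lengths (mean 50, truncated at 5% of the SD) until the budget
  $\lfloor\varepsilon_B L\rceil$ of block bases is reached;
* **then point mutations as a Poisson process**: the number of mutation
  events is Poisson($\varepsilon_P L$), positions drawn with replacement,
  each event forcing a different base. A base can be hit twice (and may
  revert), so the fraction of untouched k-mers is exactly
  $e^{-k\varepsilon_P}$ — the preservation probability the detection
  threshold assumes. Drawing a fixed count of forced substitutions
  instead would give $(1-\varepsilon_P)^k$, about 16% fewer preserved
  14-mers, and would silently detach the simulation from the model the
  threshold is derived from.

The realized edit script (changed positions + block bases over
$L + \text{insertions}$) is recorded per SD and stays within
$\varepsilon + 0.02$. Sensitivity is scored by the strict criterion that a
single call covers more than 90% of a planted SD's basepairs, source and
copy (either orientation).

What the simulator does *not* emulate: real repeat landscapes and
low-complexity sequence (inputs are assumed hard-masked), GC and mutation
heterogeneity, gene conversion between paralogs, and multi-copy (>2)
duplication events. Passing the simulation grid therefore demonstrates the
filter/alignment machinery under the stated error model, not performance
on an unmasked mammalian assembly.

## Problem sizes and numerical choices

The packaged evaluation simulates 200 SDs of 1–10 Kbp in a 5 Mbp
background per grid point $\varepsilon \in \{0.05, 0.10, 0.15, 0.20,
0.25\}$ (the full study used 1,000 SDs up to 100 Kbp on a denser grid);
each point runs in well under a minute on one CPU. Detection always runs
with the *default* model ($\varepsilon = 0.25$, $\varepsilon_P = 0.15$)
regardless of the simulated divergence, as a user without ground truth
would. Sensitivity on this configuration is ≥98% at every grid point and
~99% at $\varepsilon = 0.25$; the residual misses concentrate at ~1 Kbp,
where the realized Jaccard index of an individual SD can fall below its
expectation — and hence below $\tau$ — by chance.

Other fixed choices: k-mer codes are packed 2 bits per residue with
`A<C<G<T` (so code order equals lexicographic order where it matters, in
`encode_kmers`); ties in winnowing go to the rightmost k-mer; equal-score
alignment trims prefer the longest window; all coordinates are 0-based
half-open; SD records are kept with interval a lexicographically not
after interval b.

## Limitations

* Elementary-SD tracking across an inversion boundary is supported only
  when the minus-strand paralog is the orientation of its whole region;
  clusters mixing orientations within one merged region use the first
  contributor's orientation.
* The cross-genome stage maps known SD paralogs only, by design — a
  conserved but unduplicated region is never reported — so it cannot
  discover duplications private to an unanalyzed genome.
* Banded alignment guarantees `err` is an upper bound on the optimal edit
  error; pathological indel structures wider than the band would be split
  into separate records rather than aligned through.
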