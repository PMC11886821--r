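---
title: "Greedy and modified cosine scoring of tandem mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy and modified cosine scoring of tandem mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscosine)
```

## The scoring problem

Untargeted metabolomics identifies unknown compounds by comparing their
MS/MS fragmentation spectra ("queries") against libraries of spectra from
known compounds ("references"). The workhorse similarity is the cosine of
the angle between the two spectra's peak-intensity vectors — but because
measured fragment m/z values carry instrument error, one must first decide
*which* peaks of one spectrum correspond to which peaks of the other. Two
peaks may be paired when their m/z values differ by at most a tolerance
(0.1 Th by default here), and each peak may be used at most once, so the
pairing is an assignment problem. Solving it exactly (the "Hungarian
cosine") is too slow at library scale; the field's standard approximation
is the **greedy cosine**: collect all tolerance-feasible peak pairs, sort
them by the product of their peak weights, and accept pairs in descending
order whenever both peaks are still unused.

Writing $w_i = m_i^{p_{mz}}\, I_i^{p_{int}}$ for the weight of a peak with
m/z $m_i$ and intensity $I_i$ (defaults $p_{mz}=0$, $p_{int}=1$), the score
for an accepted pair set $A$ is

$$ S \;=\; \frac{\sum_{(i,j)\in A} w^{ref}_i\, w^{qry}_j}
  {\lVert w^{ref}\rVert_2 \; \lVert w^{qry}\rVert_2}, $$

together with the number of accepted pairs (the *match count*).

The **modified cosine** adds a second pair-collection pass in which every
fragment is expressed relative to its own precursor ion: peaks also match
when $|(m^{ref}_i - P^{ref}) - (m^{qry}_j - P^{qry})| \le$ tolerance, with
$P$ the precursor m/z. Structurally related ("analogue") molecules differ
by a mass modification that shifts a subset of fragments by exactly the
precursor mass difference; the shifted pass recovers those matches, which
the plain greedy score cannot see.

## The batched engine

Scoring a library is $R \times Q$ independent pair comparisons. The engine
mirrors the layout used by data-parallel (GPU-style) implementations while
running on the CPU:

* consecutive spectra are packed into batches of $B$ (`batch_size`,
  default 512); within a batch the peaks live in two zero-padded $M \times
  B$ planes (m/z and weight), $M$ being the longest spectrum in the batch
  after truncation to the `max_peaks` most intense peaks;
* per-slot metadata (true length, cosine norm, optionally precursor m/z)
  travels alongside, so the kernel never recomputes norms;
* the $R \times Q$ grid is tiled into $\lceil R/B\rceil \times \lceil
  Q/B\rceil$ blocks; each block cell runs the three-stage kernel (collect
  within tolerance up to the match limit → sort by weight product →
  greedy accept-and-mark) entirely independently of every other cell.

Because each cell is independent and the within-cell order is fully
deterministic, the assembled matrix is **bit-identical for every batch
size** and for every block traversal order; the test suite asserts this.
Cells are currently evaluated serially in compiled code; the independence
contract is what would allow a threaded or GPU backend without changing
any result.

### Match limit and overflow

Pair collection uses a fixed budget of `match_limit` candidate pairs per
pass (default 1024; modified cosine runs two passes, i.e. a $2N$ budget
split exactly $N + N$). If one more feasible pair is encountered after the
budget is exhausted, collection stops early and the comparison's
**overflow flag** is raised: its score was computed from a truncated
candidate list and should be treated as untrustworthy rather than silently
wrong. Raising the limit can only turn overflow off, never on, and once
the limit covers all feasible pairs the result equals the unlimited
computation — both are asserted as properties.

### Sparse output

Most library scores are near zero, so dense $R \times Q$ storage is
wasteful at scale; `score_all(..., output = "sparse")` keeps a coordinate
list of entries with score at or above `sparse_threshold`. Overflowed
entries are retained regardless of their score: an overflowed low score is
exactly the case a user may want to audit, and dropping it would hide the
flag. (Filtering applies to the score only, never to the match count.)
Dense output is refused beyond a configurable cell budget (default $10^8$
cells) with a pointer to sparse mode.

## Numerical choices

* **Tie-breaking.** Pairs with equal weight products are ordered by
  ascending (reference index, query index). Without a pinned rule the
  greedy accept order — and hence the score — depends on the sort
  implementation; pinning it makes results reproducible across platforms.
* **Tolerance boundary.** The feasibility comparison is inclusive
  (`<=`), matching the reference ecosystem's convention.
* **Duplicate pairs across modified-cosine passes.** When the precursor
  difference is below twice the tolerance, a pair can be feasible in both
  passes. It is kept once (the unshifted copy wins) and skipped duplicates
  do not consume the second pass's budget. Since both copies carry the
  same weight product, this choice affects only overflow accounting, never
  the score, but it is pinned so the oracle and kernel agree exactly.
* **Precision.** The kernel is compiled for both float64 and float32
  (`precision = "single"`); the single path performs *every* comparison
  and accumulation in float32, including the tolerance test. The practical
  error modes of float32 scoring are (a) peak pairs whose distance is
  within rounding of the tolerance boundary, where float32 rounding flips
  the inclusion decision, and (b) spectra whose norm is dominated by one
  or two huge peaks, where one flipped pair moves the score a lot.
  `verify_agreement()` measures the disagreement rate against the
  double-precision reference and verifies per violation that one of these
  two modes explains it.
* **Degenerate records.** Spectra that are empty after zero-intensity
  filtering (zero norm) score 0 with no error; a batch run never aborts on
  one bad record. Duplicate m/z values are merged at load by summing
  intensities; truncation keeps the `max_peaks` most intense peaks
  (intensity ties broken toward lower m/z) and restores m/z order.

## The reference implementations

`oracle_greedy()` re-implements the identical collect/sort/deduplicate
rule as plainly as possible — vectorised base R, full enumeration, no
batching, optionally no match limit. It is not a second code path of the
kernel: the two were written against the written rule, and the test suite
requires them to agree **bitwise** at double precision on thousands of
random pairs (and end-to-end across a full scoring grid). `oracle_optimal()`
computes the exact maximum-weight matching (via igraph's bipartite
matching) on small instances; greedy can never exceed it, and a crossing
configuration where greedy is strictly worse is constructed in the tests
and verified against exhaustive matching enumeration.

## What the synthetic generator emulates — and what it does not

`generate_library()` builds paired reference/query spectra with the
features that make matching non-trivial: variable peak counts, a
controlled fraction of shared peaks (intensities copied so that a perfect
analogue pair scores exactly 1), sub-tolerance m/z jitter on shared peaks,
decoy peaks, heavy-tailed (log-uniform over three decades) intensities
reproducing the few-dominant-peaks character of real spectra, and an
optional precursor offset that displaces every shared fragment by the
precursor mass difference. m/z positions are drawn on an integer grid
before jitter so libraries are bit-identical under a fixed seed and the
planted-match truth is exactly computable from the jitter draws (jitter is
uniform, not Gaussian, for the same reason). Under `strict_truth`, decoys
are rejection-sampled to stay two tolerances clear of anything that could
legitimately match, making the kernel's diagonal match counts equal the
planted truth exactly.

The generator does **not** simulate fragmentation chemistry: no isotope
patterns, adducts, neutral-loss series, correlated noise, or
instrument-specific peak shapes. Passing tests therefore demonstrate the
*scoring machinery* is exact and robust, not that any particular real
library will be matched well; scoring quality on real data is a property
of the cosine family itself, not of this implementation.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to exercise every code path
while keeping a full run in minutes: 10,000 pairs (5–200 peaks) for the
bitwise kernel-vs-reference comparison, 100,000 pairs for the
single-vs-double precision experiment, a 60×60 grid for batch-size
invariance, 500 small pairs plus a constructed crossing instance for the
greedy-vs-optimal bound, a 150-pair dense-overlap library for the
match-limit sweep {4, 16, 64, 256, 1024}, 50 analogue pairs at a water-loss
offset (18.0106 Th) for shift recovery, and a 100×100 grid for
sparse/dense consistency. `scripts/acceptance.R` re-runs all of these from
scratch under a caller-supplied seed.

## Known limitations

* Scoring is serial on one CPU core; the block contract permits, but the
  package does not ship, a threaded or GPU backend.
* Only MGF and NIST MSP text formats are read; mzML/mzXML are out of
  scope, as are centroiding and noise filtering beyond zero-intensity
  removal.
* The exact (Hungarian) cosine is exposed only as a small-instance bound,
  not as a production scorer.
* Sparse output is an in-memory coordinate list; out-of-core scoring and
  top-k retrieval per query are not implemented.
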