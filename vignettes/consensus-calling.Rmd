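---
title: "Consensus calling for rolling-circle concatemeric small-RNA reads"
author: "ConcatConsensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling for rolling-circle concatemeric small-RNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConcatConsensus)
```

## The problem

Small RNAs (18–60 nt) are too short, and nanopore base calling too
error-prone, for direct single-read sequencing. A rolling-circle library
strategy solves both problems at once: each small RNA is ligated to a known
adapter, the ligation product is circularized, and a strand-displacing
reverse transcriptase copies the circle many times over, producing a long
concatemeric cDNA — dozens of tandem copies of the same `insert + adapter`
unit in a single molecule. Random sequencing errors hit different copies at
different positions, so aligning the copies and taking a column-wise
majority recovers the template far more accurately than any single copy.

This package implements the informatics half of that strategy:

1. **Filter** raw reads by length and mean quality.
2. **Detect** the tandem periodic repeat inside each read by k-mer
   periodicity and segment it into repeat units.
3. **Align** the units and call a per-read consensus.
4. **Phase** the consensus — its circular start point is arbitrary — by
   enumerating rotations and anchoring the known adapter at one end, then
   trim the adapter to recover the insert.
5. **Score** inserts against references (percent identity from a local
   alignment) and **quantify** representation bias against an equimolar
   reference pool.

A seeded simulator of concatemeric reads (`simulateReads()`) generates
ground-truthed input for all of this, so the entire workflow is testable
without sequencing data.

## Read filtering

`filterReads()` keeps reads with length strictly greater than 1000 bases
and mean quality of at least 7 — the length comparison is strict and the
quality comparison inclusive, and both cutoffs are configurable through
`FilterParams()`. "Mean quality" is the arithmetic mean of the per-base
Phred scores by default. Some base callers instead report the Phred score
of the mean per-base *error probability*, which is never larger; that
variant is available as `qualityMode = "error-mean"`.

## Repeat detection

`findPeriodicRegions()` exposes six parameters, with defaults tuned for
concatemeric small-RNA reads:

| parameter | default | meaning |
|---|---|---|
| `kmerSize` | 5 | word size for periodicity detection |
| `windowSize` | 1000 | sliding window (bases), 50% overlap |
| `peakHeight` | 10 | minimum within-window occurrences of a k-mer |
| `gapThreshold` | 200 | maximum spacing (bases) between consecutive hits |
| `margin` | 200 | extension of a detected region on both sides |
| `letterConsistency` | 0.5 | column agreement threshold for the consensus |

Every k-mer of the circular template recurs once per rolled-out copy, so
template k-mers accumulate `peakHeight` occurrences within a window as soon
as the read carries that many copies. For each such candidate k-mer the
sorted hit positions are split wherever consecutive hits lie more than
`gapThreshold` apart; runs of at least `peakHeight` hits become regions,
extended by `margin` and clipped to the read; overlapping regions from
different k-mers are merged. The period is estimated per candidate k-mer as
the rounded median inter-hit spacing — robust to hits missing through
sequencing error — and the merged region takes the majority vote across its
k-mers. The median/majority construction was chosen over spectral methods
(FFT, autocorrelation) because it is exact on clean data, straightforward to
verify, and holds up at the 8–15% error rates relevant here.

Note a structural consequence of `peakHeight = 10`: reads with fewer than
ten rolled-out copies cannot reach the occurrence threshold and are
reported repeat-free. This matches the intent of consensus sequencing —
reads with very few copies cannot support an accurate consensus anyway.

**Unit segmentation.** The most frequent k-mer in the region anchors the
segmentation: the region is cut at each anchor occurrence, one cut per
copy. Two refinements make this robust:

* *Period-consistent anchor choice.* A word shared between insert and
  adapter occurs twice per copy and would cut units at alternating
  spacings; anchors are therefore screened (most frequent first) for a
  median occurrence spacing within ±25% of the period.
* *Fused-unit subdivision.* A sequencing error that destroys the anchor in
  one copy fuses two copies into a double-length interval; intervals are
  subdivided at the nearest period multiples. Occurrences closer than half
  a period to the previous cut (chance duplicates) are dropped, and partial
  flanking units shorter than half a period are discarded.

## Consensus calling

Units of one read are aligned by the center-star construction: the unit
with length closest to the median unit length (ties resolved by sequence
content, making the result invariant to unit order) is the center, every
other unit is globally aligned to it with the Needleman–Wunsch algorithm
(match +2, mismatch −3, gap open −5, gap extend −2), and the pairwise
alignments are merged over shared center coordinates. For near-identical
short tandem copies, center-star is essentially as good as a full multiple
alignment while remaining simple enough to verify against enumeration; a
partial-order aligner could be slotted in behind the same interface. Units
with lengths outside [0.5, 1.5] × the median are excluded up front —
they are almost always fusion artifacts — which also keeps the alignment
length within 1.5 × the median unit length.

Per column, the plurality symbol among `{A, C, G, T, gap}` decides the
call: a gap plurality whose frequency reaches `letterConsistency` emits
nothing; otherwise the plurality base is emitted, with base ties broken in
the fixed order A < C < G < T for reproducibility.

## Rotation phasing and adapter trimming

A consensus derived from a circle starts at an arbitrary offset.
`phaseConsensus()` enumerates all rotations and globally aligns the adapter
to each — in both orientations, because the consensus derives from cDNA and
may be either strand; the winning orientation determines the reported
strand, and minus-strand inserts are reverse-complemented back to reference
sense. The chosen rotation is the one with the longest un-gapped alignment
run that touches the first or last position of the rotated sequence
("anchored"), so that trimming the adapter leaves a contiguous insert.

Two numerical details matter. First, an un-gapped run of a forced global
alignment may consist largely of mismatches on unrelated sequence, so ties
on run length are broken by alignment score, then by lowest rotation
offset, then by the as-given orientation. Second, phasing confidence is
judged on the *matching* columns inside the winning run: fewer than half
the adapter length, or less than 80% of the run, flags the consensus
unphaseable and excludes it from downstream counting. Both thresholds are
configurable; they reject essentially all adapter-free random sequence
while tolerating one or two consensus errors inside the adapter.

The all-rotations search is quadratic in the consensus length, which is
irrelevant at the ~40–100 nt scale of these consensi; no circular-alignment
shortcut is attempted.

## Accuracy scoring

`scoreAccuracy()` computes the optimal local alignment (Smith–Waterman with
soft clipping; same scoring as above, a gap of length *g* costing 5 + 2*g*)
of each insert against the reference, and reports

> percent identity = 100 × (aligned bases − edit distance) / aligned bases,

where the edit distance counts mismatch and gap columns inside the local
alignment and the aligned bases count all its columns. The DP is
implemented in the package because the (aligned bases, edit distance)
decomposition of one specific optimal alignment is the reported statistic;
tie-breaks are fixed (first maximal cell in a row-major scan; diagonal
preferred over vertical gap over horizontal gap) so results are
reproducible, and the test suite checks the scores against an independent
aligner and the full decomposition against a naive reference
implementation. An alternative denominator — reference length instead of
aligned columns — would penalize soft-clipped truncations; the aligned-
columns form is the default and the only one reported.

## Pool quantification and bias

Inserts are assigned to members of an equimolar reference pool (e.g. a
962-member synthetic miRNA pool) by bounded nearest-neighbor matching on
Levenshtein distance: an insert maps to the unique member within distance 2,
and ambiguous or distant inserts count as unmapped. Pool members are short,
distinct sequences, so this replaces a genome-scale mapper exactly and
reproducibly. `normalizeCounts()` divides each raw count by the expected
per-member count (total mapped / pool size): a perfectly represented member
scores 1. `biasWithinTwofold()` reports the percentage of members with a
normalized count in the closed interval [0.5, 2.0] — the inclusive reading
of "within 2-fold" — and is invariant to rescaling all counts.

## The simulator

`simulateReads()` emulates the structure of rolling-circle libraries: a
circular template (insert + adapter), a uniform repeat count (default 5–50,
configurable; uniform was chosen because no empirical repeat-count
distribution is available for this protocol, and it is the simplest shape
spanning the observed range), a uniformly random phase offset with up to
one further template length truncated at the read end (first/last copies
partial, as in real reads), a memoryless per-base error channel (delete,
else substitute; insert after each emitted base), either strand, and
constant Phred qualities implied by the total error rate (optionally
jittered). Error-channel order is deliberately simple and unit-testable.

What it does **not** emulate: signal-level artifacts, homopolymer-biased or
context-dependent errors, quality variation along the read, chimeric reads,
or adapter-only circles. Passing tests on simulated data therefore
demonstrate the correctness of the algorithms under a memoryless error
model, not performance on any particular flowcell chemistry.

The bundled control sequences mirror the classic accuracy experiment: a
42-nt circular template of a 21-nt insert carrying the human miRNA
hsa-let-7a sequence (`let7aInsert()`) plus a 21-nt adapter
(`syntheticAdapter()` — a synthetic stand-in sequence, as the real library
adapter is proprietary).

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to keep the full suite in the low minutes on a single
CPU while leaving the statistics stable: 1,000 reads for the control-oligo
accuracy experiment (repeat counts uniform 10–40 so that a usable fraction
passes the 1000-base length filter; 8% total error split 50/25/25 between
substitutions, insertions and deletions), 200 reads for the error-free
recovery and repeat/length-correlation checks, and 200 random pairs for
the alignment-oracle comparison. Error-free recovery is checked on the
stage functions directly (detection → consensus → phasing) without the
length filter, which is a QC gate for real nanopore data rather than part
of the recovery machinery. Every simulation is seeded; identical seed and
configuration reproduce output byte for byte.

## Known limitations

* Reads with fewer copies than `peakHeight` are invisible to the detector
  by construction.
* A chimeric read produces several merged regions, each phased and counted
  independently; no attempt is made to reconcile them.
* The period estimate can be off by one or two bases at high error rates;
  downstream unit alignment absorbs this.
* Inserts shorter than half the adapter cannot be phased reliably, and
  adapter-only circles yield empty inserts that are flagged rather than
  counted.
* The bounded-distance pool mapper assumes pool members are mutually
  distinct at distance > 2 × the assignment bound for unambiguous counts;
  extremely similar members (e.g. isomiR families) would need a dedicated
  disambiguation strategy.
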