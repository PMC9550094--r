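# ConcatConsensus

Consensus calling and bias assessment for rolling-circle concatemeric
small-RNA nanopore reads.

## What problem this solves

Small RNAs (miRNAs, piRNAs, tRNA fragments, ...) are 18–60 nt — too short
and too error-prone to read directly on a nanopore sequencer. A
rolling-circle library strategy fixes this: each small RNA is ligated to a
known adapter, circularized, and copied many times by rolling-circle
reverse transcription, so one sequenced molecule carries dozens of tandem
copies of the same `insert + adapter` unit. Errors hit different copies at
different positions, and a per-read consensus over the copies recovers the
template with high accuracy.

This package is the informatics workflow for such libraries, aimed at
people developing or benchmarking small-RNA sequencing protocols:

* **`filterReads()`** — length (> 1000 bp, strict) and mean-quality
  (≥ 7, inclusive) read filtering.
* **`findPeriodicRegions()` / `segmentUnits()`** — tandem-repeat detection
  by k-mer periodicity (k-mer size 5, window 1000, peak height 10, gap 200,
  margin 200) and segmentation into repeat units.
* **`alignUnits()` / `callConsensus()`** — center-star alignment of the
  units and column-wise consensus with a letter-consistency threshold
  (0.5).
* **`phaseConsensus()` / `trimAdapter()`** — resolution of the arbitrary
  circular phase by rotation enumeration against the adapter
  (Needleman–Wunsch; the first rotation with the longest un-gapped
  anchored run wins) and adapter trimming.
* **`scoreAccuracy()`** — local alignment (Smith–Waterman, soft clipping)
  of each insert against a reference, reporting
  `percent identity = 100 × (aligned bases − edit distance) / aligned bases`.
* **`mapToPool()` / `normalizeCounts()` / `biasWithinTwofold()`** —
  quantification against an equimolar reference pool: normalized count =
  raw count / (total mapped / pool size), so 1.0 means perfect
  representation, and the bias summary is the percentage of members with a
  normalized count in [0.5, 2].
* **`simulateReads()`** — a seeded simulator of concatemeric reads
  (configurable substitution/insertion/deletion rates, repeat-count range,
  strand balance) with full ground truth, so every stage is testable
  offline.
* **`runPipeline()`** — all stages end to end, with per-stage outputs and
  a run summary. A command-line front end with the same stages as
  subcommands is installed at `inst/scripts/concat-tools.R`.

## Worked example

Simulate a control-oligo experiment — a 42-nt circular template of the
21-nt hsa-let-7a insert plus a 21-nt adapter, 200 reads with 10–40 tandem
copies each and 8% total per-base error — and run the full pipeline:

```r
library(ConcatConsensus)

cfg <- SimConfig(let7aInsert(), syntheticAdapter(),
                 repeatMin = 10, repeatMax = 40, nReads = 200,
                 subRate = 0.04, insRate = 0.02, delRate = 0.02, seed = 7)
sim <- simulateReads(cfg)
res <- runPipeline(sim$reads, syntheticAdapter(), references = let7aInsert())
#> filterReads: kept 107/200 reads (length > 1000, mean quality >= 7)
#> repeat detection: 107/107 reads with periodic repeats; 107 consensus sequence(s)
#> phasing: 101/107 consensus sequences phased
#> accuracy: 97/101 inserts at 100% identity

res$summary
#>          stage         n
#> 1        input       200
#> 2     filtered       107
#> 3 with_repeats       107
#> 4    consensus       107
#> 5       phased       101

accuracyHistogram(res$accuracy, thresholds = c(90, 95))
#>           bin     count  fraction
#> 1        >=90       101  1.000000
#> 2        >=95        99  0.980198
#> 3        =100        97  0.960396

head(res$inserts, 2)
#>              sim_000004              sim_000005
#> "TGAGGTAGTAGGTTGTATAGT" "TGAGGTAGTAGGTTGTATAGT"
```

Reading the output: 107 of 200 simulated reads exceed 1000 bp (shorter
concatemers carry too few copies for a reliable consensus and are
filtered), every surviving read yields a detected repeat and a consensus,
101 phase confidently against the adapter, and 96% of the recovered
21-nt inserts match the let-7a reference perfectly — single-read nanopore
error rates of ~8% collapse to near-zero in the consensus.

## Documentation

The methods vignette (`vignettes/consensus-calling.Rmd`) describes the
algorithms, their parameters and defaults, the simulator's scope, and the
package's numerical conventions (alignment scoring, tie-breaks, flagging
thresholds) in detail.
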