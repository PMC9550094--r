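Package: ConcatConsensus
Title: Consensus Calling and Bias Assessment for Rolling-Circle
    Concatemeric Small RNA Reads
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs high-accuracy small RNA sequences from noisy
    concatemeric nanopore reads produced by rolling-circle reverse
    transcription of circularized adapter-ligated small RNAs. Reads are
    length- and quality-filtered, tandem periodic repeats are detected by
    k-mer periodicity, repeat units are aligned to call a per-read
    consensus, the arbitrary circular phase is resolved by rotation
    enumeration against the known adapter, and the trimmed inserts are
    scored for accuracy against references and for representation bias
    against an equimolar reference pool. A seeded simulator of
    concatemeric reads with configurable substitution, insertion and
    deletion error rates makes the whole workflow testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: Sequencing, Alignment, SmallRNA, QualityControl, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accuracy.R'
    'consensus.R'
    'phase.R'
    'pipeline.R'
    'pool.R'
    'read-io.R'
    'repeat-finder.R'
    'simulate.R'
    'utils.R'
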