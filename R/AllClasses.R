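#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width reduce
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for k-mer periodicity repeat detection
#'
#' Holds the six tunable parameters of the tandem-repeat detector:
#' k-mer size, sliding window size, peak height threshold (minimum
#' within-window occurrence count for a k-mer to be treated as periodic),
#' gap threshold (maximum spacing between consecutive hits of a periodic
#' k-mer before the run is split), margin (extension of a detected region
#' on both sides) and the letter-consistency threshold used downstream by
#' the consensus caller. Defaults are the workflow's tuned values for
#' concatemeric small-RNA nanopore reads.
#'
#' @slot kmerSize Integer, k-mer length (default 5).
#' @slot windowSize Integer, sliding window size in bases (default 1000).
#' @slot peakHeight Integer, minimum within-window k-mer count (default 10).
#' @slot gapThreshold Integer, maximum gap between periodic k-mer hits in
#'   bases (default 200).
#' @slot margin Integer, bases added on each side of a detected region
#'   (default 200).
#' @slot letterConsistency Numeric in (0, 1], consensus column agreement
#'   threshold (default 0.5).
#' @export
setClass("RepeatParams", representation(
    kmerSize = "integer",
    windowSize = "integer",
    peakHeight = "integer",
    gapThreshold = "integer",
    margin = "integer",
    letterConsistency = "numeric"
))

setValidity("RepeatParams", function(object) {
    msg <- NULL
    if (object@kmerSize < 3L)
        msg <- c(msg, "kmerSize must be >= 3")
    if (object@windowSize <= 2L * object@kmerSize)
        msg <- c(msg, "windowSize must exceed 2 * kmerSize")
    if (object@peakHeight < 2L)
        msg <- c(msg, "peakHeight must be >= 2")
    if (object@gapThreshold < 1L)
        msg <- c(msg, "gapThreshold must be >= 1")
    if (object@margin < 0L)
        msg <- c(msg, "margin must be >= 0")
    if (object@letterConsistency <= 0 || object@letterConsistency > 1)
        msg <- c(msg, "letterConsistency must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @param kmerSize,windowSize,peakHeight,gapThreshold,margin,letterConsistency
#'   See slot documentation.
#' @return `RepeatParams()` returns a `RepeatParams` object.
#' @rdname RepeatParams-class
#' @examples
#' RepeatParams()
#' RepeatParams(kmerSize = 6, peakHeight = 5)
#' @export
RepeatParams <- function(kmerSize = 5L, windowSize = 1000L, peakHeight = 10L,
                         gapThreshold = 200L, margin = 200L,
                         letterConsistency = 0.5) {
    new("RepeatParams",
        kmerSize = as.integer(kmerSize),
        windowSize = as.integer(windowSize),
        peakHeight = as.integer(peakHeight),
        gapThreshold = as.integer(gapThreshold),
        margin = as.integer(margin),
        letterConsistency = as.numeric(letterConsistency))
}

setMethod("show", "RepeatParams", function(object) {
    cat("RepeatParams: k =", object@kmerSize,
        "| window =", object@windowSize,
        "| peak height =", object@peakHeight,
        "| gap =", object@gapThreshold,
        "| margin =", object@margin,
        "| letter consistency =", object@letterConsistency, "\n")
})

#' Read-level filter parameters
#'
#' Reads shorter than or equal to `minLength` bases, or with mean quality
#' below `minMeanQuality`, are discarded before repeat detection. The length
#' comparison is strict (`> minLength`), the quality comparison inclusive
#' (`>= minMeanQuality`). `qualityMode` selects how "average quality" is
#' computed: `"phred-mean"` (arithmetic mean of per-base Phred scores, the
#' default) or `"error-mean"` (Phred score of the mean per-base error
#' probability, as some basecallers report).
#'
#' @slot minLength Integer minimum read length, exclusive (default 1000).
#' @slot minMeanQuality Numeric minimum mean quality, inclusive (default 7).
#' @slot qualityMode Character, `"phred-mean"` or `"error-mean"`.
#' @export
setClass("FilterParams", representation(
    minLength = "integer",
    minMeanQuality = "numeric",
    qualityMode = "character"
))

setValidity("FilterParams", function(object) {
    msg <- NULL
    if (object@minLength < 0L)
        msg <- c(msg, "minLength must be >= 0")
    if (object@minMeanQuality < 0)
        msg <- c(msg, "minMeanQuality must be >= 0")
    if (!object@qualityMode %in% c("phred-mean", "error-mean"))
        msg <- c(msg, "qualityMode must be 'phred-mean' or 'error-mean'")
    if (is.null(msg)) TRUE else msg
})

#' @param minLength,minMeanQuality,qualityMode See slot documentation.
#' @return `FilterParams()` returns a `FilterParams` object.
#' @rdname FilterParams-class
#' @examples
#' FilterParams()
#' @export
FilterParams <- function(minLength = 1000L, minMeanQuality = 7,
                         qualityMode = c("phred-mean", "error-mean")) {
    new("FilterParams",
        minLength = as.integer(minLength),
        minMeanQuality = as.numeric(minMeanQuality),
        qualityMode = match.arg(qualityMode))
}

setMethod("show", "FilterParams", function(object) {
    cat("FilterParams: length >", object@minLength,
        "| mean quality >=", object@minMeanQuality,
        "(", object@qualityMode, ")\n")
})

#' Configuration of the concatemeric read simulator
#'
#' Describes a simulated rolling-circle sequencing experiment: the circular
#' templates (insert + adapter), how many tandem copies each read rolls out,
#' the per-base error channel and the strand balance. Repeat counts are drawn
#' uniformly from `repeatMin:repeatMax`; fixed counts are obtained with
#' `repeatMin == repeatMax`.
#'
#' @slot insertSequences Character vector of insert sequences (DNA; RNA `U`
#'   is transliterated at construction).
#' @slot adapter Single adapter sequence, ligated 3' of every insert on the
#'   circular template.
#' @slot repeatMin,repeatMax Integer bounds (inclusive) of the uniform
#'   repeat-count distribution; both `>= 1`.
#' @slot nReads Integer number of reads to simulate.
#' @slot subRate,insRate,delRate Per-base substitution / insertion / deletion
#'   probabilities; each `>= 0`, summing to `< 0.5`.
#' @slot strandFraction Probability that a read is emitted as the reverse
#'   complement (default 0.5).
#' @slot qualityJitter Integer; if positive, per-base Phred scores are
#'   jittered uniformly by up to this many units around the rate-implied
#'   constant score (default 0).
#' @slot seed Integer random seed; identical configuration and seed give
#'   byte-identical output.
#' @export
setClass("SimConfig", representation(
    insertSequences = "character",
    adapter = "character",
    repeatMin = "integer",
    repeatMax = "integer",
    nReads = "integer",
    subRate = "numeric",
    insRate = "numeric",
    delRate = "numeric",
    strandFraction = "numeric",
    qualityJitter = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (length(object@insertSequences) < 1L ||
        any(!nzchar(object@insertSequences)))
        msg <- c(msg, "at least one non-empty insert sequence is required")
    if (any(nchar(object@insertSequences) < 15L |
            nchar(object@insertSequences) > 200L))
        msg <- c(msg, "insert lengths must lie in [15, 200] nt")
    if (nchar(object@adapter) < 15L || nchar(object@adapter) > 40L)
        msg <- c(msg, "adapter length must lie in [15, 40] nt")
    if (object@repeatMin < 1L || object@repeatMax < object@repeatMin)
        msg <- c(msg, "need 1 <= repeatMin <= repeatMax")
    if (object@nReads < 1L)
        msg <- c(msg, "nReads must be positive")
    rates <- c(object@subRate, object@insRate, object@delRate)
    if (any(rates < 0) || sum(rates) >= 0.5)
        msg <- c(msg, "error rates must be >= 0 and sum to < 0.5")
    if (object@strandFraction < 0 || object@strandFraction > 1)
        msg <- c(msg, "strandFraction must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @param insertSequences,adapter,repeatMin,repeatMax,nReads See slots.
#' @param subRate,insRate,delRate,strandFraction,qualityJitter,seed See slots.
#' @return `SimConfig()` returns a `SimConfig` object.
#' @rdname SimConfig-class
#' @examples
#' SimConfig(let7aInsert(), syntheticAdapter(), nReads = 10, seed = 1)
#' @export
SimConfig <- function(insertSequences, adapter = syntheticAdapter(),
                      repeatMin = 5L, repeatMax = 50L, nReads = 100L,
                      subRate = 0.04, insRate = 0.02, delRate = 0.02,
                      strandFraction = 0.5, qualityJitter = 0L, seed = 1L) {
    new("SimConfig",
        insertSequences = .assertNonEmptyDna(insertSequences, "insert"),
        adapter = .assertNonEmptyDna(adapter, "adapter"),
        repeatMin = as.integer(repeatMin), repeatMax = as.integer(repeatMax),
        nReads = as.integer(nReads),
        subRate = subRate, insRate = insRate, delRate = delRate,
        strandFraction = strandFraction,
        qualityJitter = as.integer(qualityJitter),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nReads, "reads from",
        length(object@insertSequences), "template(s)\n",
        " repeats uniform [", object@repeatMin, ",", object@repeatMax, "]",
        "| sub/ins/del =", object@subRate, "/", object@insRate, "/",
        object@delRate, "| seed =", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Tandem repeat annotation of one read
#'
#' Produced by [findPeriodicRegions()]. `region` is the detected periodic
#' region on the read (1-based, closed, [IRanges::IRanges]); `period` the
#' estimated repeat-unit length; `unitIntervals` the per-copy intervals
#' obtained by cutting the region at each occurrence of the anchor k-mer;
#' `anchor` the anchoring k-mer itself.
#'
#' @slot readId Character read identifier.
#' @slot region Length-one [IRanges::IRanges] spanning the periodic region.
#' @slot period Integer estimated repeat-unit length.
#' @slot unitIntervals [IRanges::IRanges] of repeat-unit intervals, ascending
#'   and non-overlapping, contained in `region`.
#' @slot anchor Character, the anchor k-mer used for segmentation.
#' @export
setClass("RepeatAnnotation", representation(
    readId = "character",
    region = "IRanges",
    period = "integer",
    unitIntervals = "IRanges",
    anchor = "character"
))

setValidity("RepeatAnnotation", function(object) {
    msg <- NULL
    if (length(object@region) != 1L)
        msg <- c(msg, "region must be a single interval")
    if (object@period < 1L)
        msg <- c(msg, "period must be positive")
    u <- object@unitIntervals
    if (length(u) > 0L) {
        if (any(start(u) < start(object@region)) ||
            any(end(u) > end(object@region)))
            msg <- c(msg, "unit intervals must lie within the region")
        if (is.unsorted(start(u), strictly = TRUE))
            msg <- c(msg, "unit intervals must be ascending")
        if (length(u) > 1L && any(start(u)[-1L] <= end(u)[-length(u)]))
            msg <- c(msg, "unit intervals must not overlap")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "RepeatAnnotation", function(object) {
    cat("RepeatAnnotation on '", object@readId, "': region [",
        start(object@region), ", ", end(object@region), "], period ",
        object@period, ", ", length(object@unitIntervals),
        " unit(s), anchor ", object@anchor, "\n", sep = "")
})

#' Per-read consensus sequence
#'
#' Produced by [callConsensus()]: the column-wise consensus of the aligned
#' repeat units of one read, together with the number of units that voted
#' and their mean identity to the consensus.
#'
#' @slot readId Character read identifier.
#' @slot sequence Consensus sequence (non-empty DNA string).
#' @slot nUnits Integer number of repeat units behind the consensus (>= 2).
#' @slot meanUnitIdentity Numeric in [0, 1], mean per-unit agreement with the
#'   consensus over the alignment columns.
#' @export
setClass("ConsensusRecord", representation(
    readId = "character",
    sequence = "character",
    nUnits = "integer",
    meanUnitIdentity = "numeric"
))

setValidity("ConsensusRecord", function(object) {
    msg <- NULL
    if (!nzchar(object@sequence))
        msg <- c(msg, "consensus sequence must be non-empty")
    if (object@nUnits < 2L)
        msg <- c(msg, "a consensus requires at least 2 units")
    if (object@meanUnitIdentity < 0 || object@meanUnitIdentity > 1)
        msg <- c(msg, "meanUnitIdentity must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConsensusRecord", function(object) {
    cat("ConsensusRecord '", object@readId, "': ", nchar(object@sequence),
        " nt from ", object@nUnits, " units (mean identity ",
        round(object@meanUnitIdentity, 3), ")\n", sep = "")
})

#' Phased, adapter-trimmed insert
#'
#' Produced by [phaseConsensus()]. The consensus is rotated so that the
#' adapter sits flush with one end (`anchoredEnd`), the adapter interval is
#' recorded on the rotated consensus, and `insert` is the remaining
#' sequence, reverse-complemented back to reference sense when the
#' reverse-complement adapter orientation won (`strand == "-"`). A consensus
#' whose best anchored un-gapped adapter alignment is too short is flagged
#' `unphaseable` and excluded from downstream counting.
#'
#' @slot readId Character read identifier.
#' @slot insert Insert sequence after adapter removal (possibly empty when
#'   flagged).
#' @slot rotationOffset Integer 0-based rotation offset applied to the
#'   consensus.
#' @slot rotatedConsensus The rotated consensus sequence.
#' @slot adapterInterval [IRanges::IRanges] (length 1 or 0) of the adapter on
#'   the rotated consensus, 1-based closed.
#' @slot strand `"+"` if the adapter matched as given, `"-"` if its reverse
#'   complement matched.
#' @slot anchoredEnd `"start"` or `"end"`: which end of the rotated
#'   consensus the un-gapped adapter alignment touches.
#' @slot ungappedAlignmentLength Integer, length in columns of the longest
#'   anchored un-gapped adapter alignment run.
#' @slot flagged Logical; `TRUE` when the consensus could not be phased
#'   confidently (short anchored run, or empty insert).
#' @export
setClass("PhasedInsert", representation(
    readId = "character",
    insert = "character",
    rotationOffset = "integer",
    rotatedConsensus = "character",
    adapterInterval = "IRanges",
    strand = "character",
    anchoredEnd = "character",
    ungappedAlignmentLength = "integer",
    flagged = "logical"
))

setValidity("PhasedInsert", function(object) {
    msg <- NULL
    n <- nchar(object@rotatedConsensus)
    if (object@rotationOffset < 0L || object@rotationOffset >= max(n, 1L))
        msg <- c(msg, "rotationOffset must lie in [0, consensus length)")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (!object@anchoredEnd %in% c("start", "end"))
        msg <- c(msg, "anchoredEnd must be 'start' or 'end'")
    if (length(object@adapterInterval) == 1L &&
        nchar(object@insert) + width(object@adapterInterval) != n)
        msg <- c(msg, "insert plus adapter interval must tile the consensus")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PhasedInsert", function(object) {
    cat("PhasedInsert '", object@readId, "': ", nchar(object@insert),
        " nt insert, offset ", object@rotationOffset, ", strand ",
        object@strand, ", anchored at ", object@anchoredEnd,
        ", un-gapped run ", object@ungappedAlignmentLength,
        if (object@flagged) " [UNPHASEABLE]" else "", "\n", sep = "")
})

#' Per-reference count table for an equimolar pool
#'
#' Raw and normalized per-member read counts against a reference pool
#' sequenced at equimolar concentration. Normalization divides each raw
#' count by the expected per-member count, `totalMapped / poolSize`, so a
#' perfectly represented member has normalized count 1.
#'
#' @slot counts A [S4Vectors::DataFrame] with columns `reference_id`,
#'   `raw_count` and (after [normalizeCounts()]) `normalized_count`.
#' @slot poolSize Integer number of pool members.
#' @slot totalMapped Integer total reads assigned to any member.
#' @slot unmapped Integer reads not confidently assigned.
#' @export
setClass("CountTable", representation(
    counts = "DataFrame",
    poolSize = "integer",
    totalMapped = "integer",
    unmapped = "integer"
))

setValidity("CountTable", function(object) {
    msg <- NULL
    cn <- colnames(object@counts)
    if (!all(c("reference_id", "raw_count") %in% cn))
        msg <- c(msg, "counts needs 'reference_id' and 'raw_count' columns")
    else {
        if (nrow(object@counts) != object@poolSize)
            msg <- c(msg, "counts must have one row per pool member")
        if (any(object@counts$raw_count < 0))
            msg <- c(msg, "raw counts must be non-negative")
        if (sum(object@counts$raw_count) != object@totalMapped)
            msg <- c(msg, "raw counts must sum to totalMapped")
        if (anyDuplicated(object@counts$reference_id))
            msg <- c(msg, "reference ids must be distinct")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CountTable", function(object) {
    cat("CountTable:", object@poolSize, "pool members,",
        object@totalMapped, "mapped reads,", object@unmapped, "unmapped\n")
    if ("normalized_count" %in% colnames(object@counts))
        cat(" normalized counts present; within-2-fold =",
            round(biasWithinTwofold(object), 1), "%\n")
})
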