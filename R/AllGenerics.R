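#' @include AllClasses.R
NULL

#' Accessors for workflow result objects
#'
#' `readId()` returns the identifier of the read a result derives from;
#' `nUnits()` the number of repeat units; `period()` the estimated
#' repeat-unit length; `unitIntervals()` and `repeatRegion()` the unit and
#' region intervals of a [RepeatAnnotation-class]; `consensusSequence()` the
#' called consensus of a [ConsensusRecord-class]; `insertSequence()` the
#' adapter-trimmed insert of a [PhasedInsert-class]; `isUnphaseable()` its
#' flag; `poolCounts()` the per-member count table of a [CountTable-class].
#'
#' @param x A result object.
#' @return The slot value (see Details of each class).
#' @name accessors
#' @examples
#' ann <- findPeriodicRegions(strrep("ACGTTGCAGGTACCGATTAGCTAGGACTGTACGGTACTTAGC", 12),
#'                            RepeatParams(windowSize = 200))[[1]]
#' period(ann)
#' nUnits(ann)
NULL

#' @rdname accessors
#' @export
setGeneric("readId", function(x) standardGeneric("readId"))

#' @rdname accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname accessors
#' @export
setGeneric("unitIntervals", function(x) standardGeneric("unitIntervals"))

#' @rdname accessors
#' @export
setGeneric("repeatRegion", function(x) standardGeneric("repeatRegion"))

#' @rdname accessors
#' @export
setGeneric("anchorKmer", function(x) standardGeneric("anchorKmer"))

#' @rdname accessors
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname accessors
#' @export
setGeneric("insertSequence", function(x) standardGeneric("insertSequence"))

#' @rdname accessors
#' @export
setGeneric("isUnphaseable", function(x) standardGeneric("isUnphaseable"))

#' @rdname accessors
#' @export
setGeneric("poolCounts", function(x) standardGeneric("poolCounts"))

#' @rdname trimAdapter
#' @export
setGeneric("trimAdapter", function(phased, ...) standardGeneric("trimAdapter"))

#' @rdname normalizeCounts
#' @export
setGeneric("normalizeCounts", function(table, ...)
    standardGeneric("normalizeCounts"))

#' @rdname biasWithinTwofold
#' @export
setGeneric("biasWithinTwofold", function(table, ...)
    standardGeneric("biasWithinTwofold"))

## accessor methods -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("readId", "RepeatAnnotation", function(x) x@readId)
#' @rdname accessors
#' @export
setMethod("readId", "ConsensusRecord", function(x) x@readId)
#' @rdname accessors
#' @export
setMethod("readId", "PhasedInsert", function(x) x@readId)

#' @rdname accessors
#' @export
setMethod("nUnits", "RepeatAnnotation", function(x) length(x@unitIntervals))
#' @rdname accessors
#' @export
setMethod("nUnits", "ConsensusRecord", function(x) x@nUnits)

#' @rdname accessors
#' @export
setMethod("period", "RepeatAnnotation", function(x) x@period)

#' @rdname accessors
#' @export
setMethod("unitIntervals", "RepeatAnnotation", function(x) x@unitIntervals)

#' @rdname accessors
#' @export
setMethod("repeatRegion", "RepeatAnnotation", function(x) x@region)

#' @rdname accessors
#' @export
setMethod("anchorKmer", "RepeatAnnotation", function(x) x@anchor)

#' @rdname accessors
#' @export
setMethod("consensusSequence", "ConsensusRecord", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("insertSequence", "PhasedInsert", function(x) x@insert)

#' @rdname accessors
#' @export
setMethod("isUnphaseable", "PhasedInsert", function(x) x@flagged)

#' @rdname accessors
#' @export
setMethod("poolCounts", "CountTable", function(x) x@counts)
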