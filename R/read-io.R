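#' Read nanopore reads from FASTQ
#'
#' Wraps [Biostrings::readQualityScaledDNAStringSet()]; gzip-compressed
#' files are handled transparently. Qualities are interpreted as Phred+33.
#'
#' @param path Path to a FASTQ (optionally `.gz`) file.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeSimulatedReads(simulateReads(SimConfig(let7aInsert(), nReads = 2,
#'                                             seed = 1)), fq)
#' readNanoporeReads(fq)
#' @export
readNanoporeReads <- function(path) {
    if (!file.exists(path))
        stop("FASTQ file not found: ", path)
    ## Biostrings warns about dropping its own internal metadata columns
    ## when re-wrapping the qualities; harmless here
    suppressWarnings(
        Biostrings::readQualityScaledDNAStringSet(path,
                                                  quality.scoring = "phred"))
}

#' Mean per-read quality
#'
#' The read-level "average quality" used by the length/quality filter.
#' `"phred-mean"` (default) is the arithmetic mean of the per-base Phred
#' scores; `"error-mean"` converts per-base scores to error probabilities,
#' averages those, and reports the Phred score of the mean error
#' probability (always less than or equal to the Phred mean).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param mode `"phred-mean"` or `"error-mean"`.
#' @return Numeric vector of mean qualities, one per read.
#' @examples
#' sim <- simulateReads(SimConfig(let7aInsert(), nReads = 3, seed = 1))
#' meanQuality(sim$reads)
#' @export
meanQuality <- function(reads, mode = c("phred-mean", "error-mean")) {
    mode <- match.arg(mode)
    if (length(reads) == 0L) return(numeric(0L))
    if (any(Biostrings::width(reads) == 0L))
        stop("mean quality is undefined for an empty read")
    qi <- as(Biostrings::quality(reads), "IntegerList")
    if (mode == "phred-mean") {
        unname(sum(qi) / lengths(qi))
    } else {
        -10 * log10(vapply(qi, function(q) mean(10^(-q / 10)), numeric(1L)))
    }
}

#' Filter reads by length and mean quality
#'
#' Keeps reads whose length is strictly greater than `minLength` and whose
#' mean quality is at least `minMeanQuality` (strict length, inclusive
#' quality). Input order is preserved and the operation is idempotent.
#' Kept/dropped counts are stored in `metadata()` of the result and
#' reported via `message()`.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param params A [FilterParams-class].
#' @param verbose Emit a one-line summary message (default `TRUE`).
#' @return The filtered [Biostrings::QualityScaledDNAStringSet]; its
#'   `metadata()` holds `nInput`, `nKept`, `nDropped`.
#' @examples
#' sim <- simulateReads(SimConfig(let7aInsert(), nReads = 20, repeatMin = 10,
#'                                repeatMax = 40, seed = 1))
#' flt <- filterReads(sim$reads, FilterParams(minLength = 500))
#' S4Vectors::metadata(flt)
#' @export
filterReads <- function(reads, params = FilterParams(), verbose = TRUE) {
    stopifnot(is(params, "FilterParams"))
    validObject(params)
    n <- length(reads)
    if (n == 0L) {
        keep <- logical(0L)
    } else {
        keep <- Biostrings::width(reads) > params@minLength &
            meanQuality(reads, params@qualityMode) >= params@minMeanQuality
    }
    out <- reads[keep]
    metadata(out) <- list(nInput = n, nKept = sum(keep),
                          nDropped = n - sum(keep))
    if (verbose)
        message("filterReads: kept ", sum(keep), "/", n,
                " reads (length > ", params@minLength,
                ", mean quality >= ", params@minMeanQuality, ")")
    out
}

#' Write reads as FASTA (qualities discarded)
#'
#' Downstream repeat detection works on bases only; this writes the
#' FASTA conversion of a (typically filtered) read set.
#'
#' @param reads A DNA string set (qualities, if any, are dropped).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
writeReadsFasta <- function(reads, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
    invisible(path)
}
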