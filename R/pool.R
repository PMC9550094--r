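## Quantification against an equimolar reference pool: nearest-neighbor
## assignment of inserts to pool members under a bounded Levenshtein
## distance, normalization to the expected per-member count, and the
## within-2-fold bias summary.

#' Assign inserts to members of a reference pool
#'
#' Each insert is assigned to the pool member with the minimum Levenshtein
#' edit distance, provided that distance is at most `maxDist` and the best
#' hit is unique; ambiguous (tied best hits) or distant inserts are counted
#' as unmapped. Pool members are short, distinct sequences, so bounded
#' nearest-neighbor matching replaces a genome-scale mapper.
#'
#' @param inserts Character vector of insert sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param pool Named character vector or [Biostrings::DNAStringSet] of pool
#'   reference sequences with distinct ids, or a FASTA path.
#' @param maxDist Maximum edit distance for an assignment (default 2).
#' @return A [CountTable-class] with raw counts per pool member.
#' @examples
#' pool <- c(mirA = "ACGTACGTACGTACGTACGT", mirB = "TTTTGGGGCCCCAAAATTTT")
#' ct <- mapToPool(c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTAT"), pool)
#' poolCounts(ct)
#' @export
mapToPool <- function(inserts, pool, maxDist = 2L) {
    if (is.character(pool) && length(pool) == 1L && is.null(names(pool)) &&
        file.exists(pool))
        pool <- Biostrings::readDNAStringSet(pool)
    poolSeq <- asDna(as.character(pool))
    ids <- names(pool)
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
        stop("pool members must carry distinct, non-empty ids")
    if (length(poolSeq) == 0L)
        stop("pool is empty")
    inserts <- asDna(as.character(inserts), allowN = TRUE)

    raw <- structure(integer(length(poolSeq)), names = ids)
    unmapped <- 0L
    if (length(inserts) > 0L) {
        d <- adist(inserts, poolSeq)
        for (i in seq_along(inserts)) {
            mn <- min(d[i, ])
            hits <- which(d[i, ] == mn)
            if (mn <= maxDist && length(hits) == 1L)
                raw[hits] <- raw[hits] + 1L
            else
                unmapped <- unmapped + 1L
        }
    }
    new("CountTable",
        counts = DataFrame(reference_id = ids, raw_count = unname(raw)),
        poolSize = length(poolSeq),
        totalMapped = as.integer(sum(raw)),
        unmapped = unmapped)
}

#' Build a count table from precomputed per-reference counts
#'
#' For workflows where mapping was done elsewhere: wraps a named vector of
#' raw counts (one entry per pool member) into a [CountTable-class].
#'
#' @param rawCounts Named integer vector, one element per pool member.
#' @param unmapped Number of unassigned reads (default 0).
#' @return A [CountTable-class].
#' @examples
#' countTable(c(mirA = 5L, mirB = 15L))
#' @export
countTable <- function(rawCounts, unmapped = 0L) {
    if (is.null(names(rawCounts)))
        stop("rawCounts must be named by reference id")
    new("CountTable",
        counts = DataFrame(reference_id = names(rawCounts),
                           raw_count = as.integer(unname(rawCounts))),
        poolSize = length(rawCounts),
        totalMapped = as.integer(sum(rawCounts)),
        unmapped = as.integer(unmapped))
}

#' Read a count table from TSV
#'
#' Expects columns `reference_id` and `raw_count`.
#'
#' @param path TSV path.
#' @inheritParams countTable
#' @return A [CountTable-class].
#' @export
readCountTable <- function(path, unmapped = 0L) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("reference_id", "raw_count") %in% colnames(tab)))
        stop("count TSV needs 'reference_id' and 'raw_count' columns")
    countTable(structure(tab$raw_count, names = tab$reference_id), unmapped)
}

#' Normalize counts against the equimolar expectation
#'
#' The pool is equimolar, so every member is expected to receive
#' `totalMapped / poolSize` reads. Each raw count is divided by this
#' expected count: a member sequenced at exactly its expected depth gets
#' normalized count 1; over- and under-represented members get values
#' above and below 1.
#'
#' @param table A [CountTable-class] with `totalMapped > 0`.
#' @param ... Unused.
#' @return The table with a `normalized_count` column filled in.
#' @examples
#' ct <- countTable(c(a = 20L, b = 10L, c = 0L))
#' poolCounts(normalizeCounts(ct))
#' @export
setMethod("normalizeCounts", "CountTable", function(table, ...) {
    if (table@totalMapped <= 0L)
        stop("cannot normalize: no mapped reads")
    expected <- table@totalMapped / table@poolSize
    table@counts$normalized_count <- table@counts$raw_count / expected
    validObject(table)
    table
})

#' Fraction of pool members within 2-fold of the expected count
#'
#' The bias summary of an equimolar-pool experiment: the percentage of
#' pool members whose normalized count lies in the closed interval
#' `[0.5, 2.0]`. 100 means a perfectly unbiased library; the metric is
#' invariant to rescaling all raw counts by a common factor.
#'
#' @param table A [CountTable-class]; normalization is applied first if the
#'   `normalized_count` column is missing.
#' @param ... Unused.
#' @return A single numeric percentage in [0, 100].
#' @examples
#' biasWithinTwofold(countTable(c(a = 10L, b = 11L, c = 9L)))
#' @export
setMethod("biasWithinTwofold", "CountTable", function(table, ...) {
    if (!"normalized_count" %in% colnames(table@counts))
        table <- normalizeCounts(table)
    nv <- table@counts$normalized_count
    100 * mean(nv >= 0.5 & nv <= 2.0)
})

#' Write a count table as TSV
#'
#' @param table A [CountTable-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(table, path) {
    write.table(as.data.frame(table@counts), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
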