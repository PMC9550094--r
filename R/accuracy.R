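## Accuracy scoring of trimmed consensus inserts against a known reference:
## optimal local alignment with soft clipping (Smith-Waterman, affine gaps),
## then percent identity defined as the edit distance (mismatch plus gap
## columns inside the local alignment) subtracted from the number of aligned
## bases (alignment columns), divided by the aligned bases.
##
## The DP is implemented here because the (aligned bases, edit distance)
## decomposition of a specific optimal alignment is the statistic of
## interest; tie-breaks are fixed so the result is reproducible: the best
## cell is the first maximum in a row-major scan, and the traceback prefers
## diagonal over vertical-gap over horizontal-gap moves. Scoring: match +2,
## mismatch -3, gap open -5, gap extend -2 (a gap of length g costs
## 5 + 2 g, as in Biostrings).

.swAlign <- function(a, b, match = 2, mismatch = -3, gapOpen = 5,
                     gapExt = 2) {
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    m <- length(av); n <- length(bv)
    NEG <- -1e9
    H <- matrix(0, m + 1L, n + 1L)
    E <- matrix(NEG, m + 1L, n + 1L)   # gap in a (consumes b)
    F <- matrix(NEG, m + 1L, n + 1L)   # gap in b (consumes a)
    ptr <- matrix(0L, m + 1L, n + 1L)  # 0 stop, 1 diag, 2 F(up), 3 E(left)
    eFromH <- matrix(FALSE, m + 1L, n + 1L)
    fFromH <- matrix(FALSE, m + 1L, n + 1L)
    bestScore <- 0; bestI <- 0L; bestJ <- 0L
    openCost <- gapOpen + gapExt

    for (i in seq_len(m)) {
        ii <- i + 1L
        for (j in seq_len(n)) {
            jj <- j + 1L
            eo <- H[ii, jj - 1L] - openCost
            ee <- E[ii, jj - 1L] - gapExt
            E[ii, jj] <- max(eo, ee)
            eFromH[ii, jj] <- eo >= ee
            fo <- H[ii - 1L, jj] - openCost
            fe <- F[ii - 1L, jj] - gapExt
            F[ii, jj] <- max(fo, fe)
            fFromH[ii, jj] <- fo >= fe
            d <- H[ii - 1L, jj - 1L] +
                (if (av[i] == bv[j]) match else mismatch)
            h <- max(0, d, F[ii, jj], E[ii, jj])
            p <- 0L
            if (h > 0) {
                if (d == h) p <- 1L
                else if (F[ii, jj] == h) p <- 2L
                else p <- 3L
            }
            H[ii, jj] <- h
            ptr[ii, jj] <- p
            if (h > bestScore) {
                bestScore <- h; bestI <- ii; bestJ <- jj
            }
        }
    }

    if (bestScore <= 0)
        return(list(score = 0, alignedBases = 0L, editDistance = 0L,
                    matches = 0L, flagged = TRUE))

    i <- bestI; j <- bestJ
    nMatch <- 0L; nMismatch <- 0L; nGap <- 0L
    state <- "H"
    repeat {
        if (state == "H") {
            p <- ptr[i, j]
            if (p == 0L) break
            if (p == 1L) {
                if (av[i - 1L] == bv[j - 1L]) nMatch <- nMatch + 1L
                else nMismatch <- nMismatch + 1L
                i <- i - 1L; j <- j - 1L
            } else if (p == 2L) state <- "F" else state <- "E"
        } else if (state == "F") {
            nGap <- nGap + 1L
            fromH <- fFromH[i, j]
            i <- i - 1L
            if (fromH) state <- "H"
        } else {
            nGap <- nGap + 1L
            fromH <- eFromH[i, j]
            j <- j - 1L
            if (fromH) state <- "H"
        }
    }
    list(score = bestScore, alignedBases = nMatch + nMismatch + nGap,
         editDistance = nMismatch + nGap, matches = nMatch, flagged = FALSE)
}

#' Score insert accuracy against a reference
#'
#' Computes the optimal local alignment (Smith-Waterman with soft clipping;
#' match +2, mismatch -3, gap open -5, gap extend -2) of each insert
#' against the reference. The edit distance — mismatches, insertions and
#' deletions within the local alignment — is subtracted from the number of
#' aligned bases (alignment columns) to give the percent identity:
#' `100 * (aligned_bases - edit_distance) / aligned_bases`. Inserts with no
#' positive-scoring local alignment get percent identity 0 and are flagged.
#'
#' @param inserts Character vector of insert sequences.
#' @param reference The reference sequence.
#' @param ids Optional identifiers for the result rows.
#' @return A [S4Vectors::DataFrame] with columns `read_id`,
#'   `aligned_bases`, `edit_distance`, `percent_identity`, `flagged`.
#' @examples
#' scoreAccuracy(let7aInsert(), let7aInsert())          # 100%
#' scoreAccuracy("TGAGGTAGTACGTTGTATAGT", let7aInsert()) # one mismatch
#' @export
scoreAccuracy <- function(inserts, reference, ids = NULL) {
    inserts <- asDna(inserts, allowN = TRUE)
    reference <- .assertNonEmptyDna(reference, "reference")[1L]
    if (length(inserts) == 0L || any(!nzchar(inserts)))
        stop("inserts must be non-empty sequences")
    if (is.null(ids))
        ids <- if (!is.null(names(inserts))) names(inserts)
               else sprintf("insert_%d", seq_along(inserts))
    res <- lapply(inserts, .swAlign, b = reference)
    ab <- vapply(res, `[[`, integer(1L), "alignedBases")
    ed <- vapply(res, `[[`, integer(1L), "editDistance")
    fl <- vapply(res, `[[`, logical(1L), "flagged")
    pid <- ifelse(ab > 0L, 100 * (ab - ed) / ab, 0)
    DataFrame(read_id = ids, aligned_bases = ab, edit_distance = ed,
              percent_identity = pid, flagged = fl)
}

#' Accuracy histogram over identity thresholds
#'
#' Counts and fractions of records reaching at least each identity
#' threshold, plus a row for exact 100% identity.
#'
#' @param records The [S4Vectors::DataFrame] returned by [scoreAccuracy()],
#'   or a numeric vector of percent identities.
#' @param thresholds Numeric thresholds in percent (default
#'   `c(80, 90, 95)`).
#' @return A [S4Vectors::DataFrame] with columns `bin`, `count`,
#'   `fraction`; rows `>=T` for each threshold and a final `=100` row.
#' @examples
#' accuracyHistogram(c(100, 95.2, 80))
#' @export
accuracyHistogram <- function(records, thresholds = c(80, 90, 95)) {
    pid <- if (is.numeric(records)) records else records$percent_identity
    if (length(pid) == 0L)
        stop("accuracy histogram of an empty record set")
    nGe <- vapply(thresholds, function(t) sum(pid >= t), integer(1L))
    n100 <- sum(pid == 100)
    DataFrame(
        bin = c(sprintf(">=%g", thresholds), "=100"),
        count = c(nGe, n100),
        fraction = c(nGe, n100) / length(pid))
}
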