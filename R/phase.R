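## Rotation phasing: a consensus derived from a circular template carries an
## arbitrary start point. All rotations are enumerated and the adapter is
## globally aligned (Needleman-Wunsch) to each rotation in both orientations;
## the first rotation (lowest offset) achieving the longest un-gapped
## alignment run that touches the start or the end of the rotated sequence
## wins, placing the adapter flush with one end so that trimming leaves a
## contiguous insert.

#' Enumerate all cyclic rotations of a sequence
#'
#' @param x A single non-empty sequence.
#' @return Character vector of the `nchar(x)` rotations, in offset order
#'   `0 .. nchar(x) - 1`.
#' @examples
#' enumerateRotations("ACG")  # "ACG" "CGA" "GAC"
#' @export
enumerateRotations <- function(x) {
    x <- .assertNonEmptyDna(x, "sequence", allowN = TRUE)
    stopifnot(length(x) == 1L)
    vapply(seq_len(nchar(x)) - 1L, function(o) rotateSequence(x, o),
           character(1L))
}

## For one gapped alignment (pattern = rotation, subject = adapter), find the
## longest run of gap-free columns that covers rotation position 1 or n.
## Returns run length, which end it touches, and the rotation positions
## spanned by the adapter (aligned columns only). The gapped strings are
## the alignment views clipped to the mutually aligned region; `rotStart`
## is the 1-based rotation position of the first view column. Clipped
## terminal columns have a gap on one side and can belong to neither a
## gap-free run nor the coverage.
.anchoredRun <- function(rotGapped, adGapped, rotStart, n, adLen) {
    p <- strsplit(rotGapped, "", fixed = TRUE)[[1L]]
    q <- strsplit(adGapped, "", fixed = TRUE)[[1L]]
    rpos <- rotStart - 1L + cumsum(p != "-")
    both <- p != "-" & q != "-"
    if (!any(both))
        return(list(run = 0L, end = "start", covStart = NA_integer_,
                    covEnd = NA_integer_))
    isMatch <- both & p == q
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bestRun <- 0L; bestEnd <- "start"; bestMatches <- 0L
    for (i in which(r$values)) {
        lo <- rpos[starts[i]]; hi <- rpos[ends[i]]
        touchesStart <- lo == 1L
        touchesEnd <- hi == n
        if (!touchesStart && !touchesEnd) next
        len <- r$lengths[i]
        if (len > bestRun) {
            bestRun <- len
            bestEnd <- if (touchesStart) "start" else "end"
            bestMatches <- sum(isMatch[starts[i]:ends[i]])
        }
    }
    ## adapter footprint on the rotation: aligned columns within roughly
    ## one adapter length of the anchored end (small slack for indels);
    ## stray aligned columns far from the anchor must not widen the
    ## trimmed interval
    if (bestRun > 0L) {
        if (bestEnd == "start") {
            sel <- both & rpos <= adLen + 5L
            covStart <- 1L
            covEnd <- max(rpos[sel])
        } else {
            sel <- both & rpos >= n - adLen - 4L
            covStart <- min(rpos[sel])
            covEnd <- n
        }
    } else {
        cov <- range(rpos[both])
        covStart <- cov[1L]
        covEnd <- cov[2L]
    }
    list(run = bestRun, end = bestEnd, matches = bestMatches,
         covStart = covStart, covEnd = covEnd)
}

#' Resolve the circular phase of a consensus against the adapter
#'
#' Globally aligns the adapter — as given and reverse-complemented, since
#' the consensus derives from cDNA of either strand — to every rotation of
#' the consensus, and picks the rotation achieving the longest un-gapped
#' alignment run anchored at the start or end of the rotated sequence. A
#' gap-free run may contain mismatches, so ties on run length are broken
#' by the alignment score, then by the lowest rotation offset ("the first
#' rotation"), then by the as-given orientation. The adapter
#' interval on the winning rotation is snapped to the anchored end and
#' removed; a minus-strand insert is reverse-complemented back to reference
#' sense. Because a gap-free run may be mismatch-rich on unrelated
#' sequence, confidence is judged on the matching columns inside the
#' winning run: fewer than `minRunFrac` times the adapter length (or an
#' empty insert) flags the result unphaseable.
#'
#' @param consensus A [ConsensusRecord-class] or a single sequence.
#' @param adapter The adapter sequence.
#' @param minRunFrac Minimum number of matching columns inside the winning
#'   anchored run, as a fraction of the adapter length, below which the
#'   consensus is flagged (default 0.5).
#' @param readId Identifier when `consensus` is a bare sequence.
#' @return A [PhasedInsert-class].
#' @examples
#' tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' ph <- phaseConsensus(rotateSequence(tpl, 10), syntheticAdapter())
#' insertSequence(ph) == let7aInsert()
#' @export
phaseConsensus <- function(consensus, adapter, minRunFrac = 0.5,
                           readId = "consensus") {
    if (is(consensus, "ConsensusRecord")) {
        readId <- consensus@readId
        s <- consensus@sequence
    } else {
        s <- .assertNonEmptyDna(consensus, "consensus", allowN = TRUE)[1L]
    }
    adapter <- .assertNonEmptyDna(adapter, "adapter")
    n <- nchar(s)
    if (n <= 0.5 * nchar(adapter))
        stop("consensus is too short to phase against the adapter")

    rots <- enumerateRotations(s)
    mat <- .nucMatrix()
    runsByOrient <- lapply(c("+", "-"), function(orient) {
        asq <- if (orient == "+") adapter else revComp(adapter)
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAStringSet(rots), Biostrings::DNAString(asq),
            type = "global", substitutionMatrix = mat,
            gapOpening = 5, gapExtension = 2)
        pat <- Biostrings::pattern(aln)
        rotG <- as.character(pat)
        adG <- as.character(Biostrings::subject(aln))
        rotStart <- start(pat)
        sc <- Biostrings::score(aln)
        lapply(seq_along(rots), function(o) {
            r <- .anchoredRun(rotG[o], adG[o], rotStart[o], n,
                              nchar(adapter))
            if (r$run == 0L) r$matches <- 0L
            r$score <- sc[o]
            r
        })
    })
    ## The winner maximises the anchored un-gapped run length; a gap-free
    ## run may contain mismatches, so ties (typically between the two
    ## adapter orientations) are resolved by the Needleman-Wunsch score,
    ## then by the lowest rotation offset ("the first rotation"), then by
    ## the as-given adapter orientation.
    best <- NULL
    for (o in seq_along(rots)) {
        for (oi in 1:2) {
            r <- runsByOrient[[oi]][[o]]
            if (is.null(best) || r$run > best$run ||
                (r$run == best$run && r$score > best$score))
                best <- list(offset = o - 1L,
                             orient = c("+", "-")[oi], run = r$run,
                             matches = r$matches, score = r$score,
                             end = r$end, covStart = r$covStart,
                             covEnd = r$covEnd)
        }
    }

    rot <- rots[best$offset + 1L]
    if (best$run > 0L && !is.na(best$covStart)) {
        if (best$end == "start") {
            aStart <- 1L; aEnd <- best$covEnd
        } else {
            aStart <- best$covStart; aEnd <- n
        }
        insert <- if (best$end == "start") substr(rot, aEnd + 1L, n)
                  else substr(rot, 1L, aStart - 1L)
        interval <- IRanges(aStart, aEnd)
    } else {
        insert <- rot
        interval <- IRanges()
    }
    if (best$orient == "-" && nzchar(insert))
        insert <- revComp(insert)
    ## a gap-free run can be mismatch-rich on unrelated sequence, so the
    ## confidence flag counts the matching columns inside the winning run
    ## and additionally requires them to dominate the run (>= 80%):
    ## unrelated sequence rarely offers a long anchored run that is mostly
    ## matches, while a consensus with a stray error in the adapter still
    ## passes comfortably
    flagged <- best$matches < minRunFrac * nchar(adapter) ||
        (best$run > 0L && best$matches / best$run < 0.8) ||
        !nzchar(insert)
    if (flagged && !nzchar(insert))
        warning("adapter interval covers the whole consensus of read '",
                readId, "': empty insert")
    new("PhasedInsert", readId = readId, insert = insert,
        rotationOffset = as.integer(best$offset), rotatedConsensus = rot,
        adapterInterval = interval, strand = best$orient,
        anchoredEnd = best$end,
        ungappedAlignmentLength = as.integer(best$run), flagged = flagged)
}

#' Trim the adapter from a phased consensus
#'
#' Removes the adapter interval from the rotated consensus, returning the
#' insert in reference sense (minus-strand inserts are
#' reverse-complemented). An empty result triggers a warning.
#'
#' @param phased A [PhasedInsert-class] (not flagged unphaseable).
#' @param ... Unused.
#' @return The insert sequence (character scalar).
#' @examples
#' tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' trimAdapter(phaseConsensus(tpl, syntheticAdapter()))
#' @export
setMethod("trimAdapter", "PhasedInsert", function(phased, ...) {
    if (phased@flagged)
        stop("cannot trim an unphaseable consensus (read '",
             phased@readId, "')")
    rot <- phased@rotatedConsensus
    n <- nchar(rot)
    iv <- phased@adapterInterval
    if (length(iv) == 0L) return(rot)
    out <- if (start(iv) == 1L) substr(rot, end(iv) + 1L, n)
           else substr(rot, 1L, start(iv) - 1L)
    if (!nzchar(out))
        warning("adapter interval covers the whole consensus; empty insert")
    if (phased@strand == "-" && nzchar(out)) out <- revComp(out)
    out
})

#' Write phased inserts as FASTA plus a phasing report
#'
#' @param phased List of [PhasedInsert-class] objects.
#' @param fasta Output FASTA path for the (unflagged, non-empty) inserts.
#' @param reportTsv Optional TSV path for the per-read phasing report
#'   (offset, strand, anchored end, run length, flag).
#' @return Invisibly, `fasta`.
#' @export
writeInsertsFasta <- function(phased, fasta, reportTsv = NULL) {
    ok <- vapply(phased, function(p) !p@flagged && nzchar(p@insert),
                 logical(1L))
    x <- Biostrings::DNAStringSet(vapply(phased[ok], function(p) p@insert,
                                         character(1L)))
    names(x) <- vapply(phased[ok], function(p) p@readId, character(1L))
    Biostrings::writeXStringSet(x, fasta)
    if (!is.null(reportTsv)) {
        rep <- do.call(rbind, lapply(phased, function(p)
            data.frame(read_id = p@readId, rotation_offset = p@rotationOffset,
                       strand = p@strand, anchored_end = p@anchoredEnd,
                       ungapped_run = p@ungappedAlignmentLength,
                       unphaseable = p@flagged)))
        write.table(rep, reportTsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(fasta)
}
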