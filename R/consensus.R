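## Center-star multiple alignment of near-identical repeat units, followed
## by column-wise consensus calling with a letter-consistency threshold.

## match +2, mismatch -3; N is neutral so stray ambiguous calls neither
## attract nor repel the alignment
.nucMatrix <- function() {
    m <- matrix(-3, 5L, 5L,
                dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
    diag(m) <- 2
    m["N", ] <- 0
    m[, "N"] <- 0
    m
}

## Global pairwise alignment of each unit against the center sequence.
## Returns the gapped alignment views clipped to the mutually aligned
## region (terminal overhangs trimmed; equal-length strings) plus the
## 1-based start of the clipped region on the center. Unit characters
## overhanging the center ends are dropped: they would form gap-majority
## columns that never reach the consensus.
.alignToCenter <- function(units, center) {
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(units), Biostrings::DNAString(center),
        type = "global", substitutionMatrix = .nucMatrix(),
        gapOpening = 5, gapExtension = 2)
    subj <- Biostrings::subject(aln)
    list(unit = as.character(Biostrings::pattern(aln)),
         center = as.character(subj),
         centerStart = start(subj))
}

#' Align the repeat units of one read
#'
#' Builds a multiple alignment of the repeat units by the center-star
#' construction: the unit whose length is closest to the median unit length
#' is the center; every other unit is globally aligned to it
#' (Needleman-Wunsch, match +2, mismatch -3, gap open -5, gap extend -2)
#' and the pairwise alignments are merged over the shared center
#' coordinates. Units with length outside `[0.5, 1.5]` times the median
#' unit length (e.g. doubled units arising when the anchor k-mer was lost
#' to a sequencing error) are excluded before alignment.
#'
#' @param units Character vector of unit sequences (at least 2 usable).
#' @return A character matrix with one row per retained unit and one column
#'   per alignment position; gaps are `"-"`. Row order follows the input
#'   (dropped units omitted).
#' @examples
#' alignUnits(c("ACGT", "AGT"))
#' @export
alignUnits <- function(units) {
    units <- asDna(units)
    if (length(units) < 2L)
        stop("consensus skipped: fewer than 2 repeat units")
    med <- median(nchar(units))
    keep <- nchar(units) >= 0.5 * med & nchar(units) <= 1.5 * med &
        nchar(units) > 0L
    units <- units[keep]
    if (length(units) < 2L)
        stop("consensus skipped: fewer than 2 usable repeat units")
    ## center = unit with length closest to the median; ties resolved by
    ## sequence content so the alignment (and consensus) is invariant to
    ## unit order
    dist <- abs(nchar(units) - median(nchar(units)))
    cands <- which(dist == min(dist))
    center <- min(units[cands])
    L <- nchar(center)

    gapped <- .alignToCenter(units, center)
    nu <- length(units)
    alignedAtCenter <- matrix("-", nu, L)
    insChars <- vector("list", nu)   # per unit: list over slots 0..L
    maxIns <- integer(L + 1L)

    for (i in seq_len(nu)) {
        cs <- strsplit(gapped$center[i], "", fixed = TRUE)[[1L]]
        ps <- strsplit(gapped$unit[i], "", fixed = TRUE)[[1L]]
        isC <- cs != "-"
        ## center position reached per column (clipped view starts at
        ## centerStart; positions outside the view stay gapped)
        slot <- gapped$centerStart[i] - 1L + cumsum(isC)
        alignedAtCenter[i, slot[isC]] <- ps[isC]
        insIdx <- which(!isC)
        sl <- vector("list", L + 1L)
        if (length(insIdx) > 0L) {
            bySlot <- split(ps[insIdx], slot[insIdx])
            for (nm in names(bySlot)) {
                s0 <- as.integer(nm) + 1L
                sl[[s0]] <- bySlot[[nm]]
                maxIns[s0] <- max(maxIns[s0], length(bySlot[[nm]]))
            }
        }
        insChars[[i]] <- sl
    }

    ncolTot <- L + sum(maxIns)
    out <- matrix("-", nu, ncolTot)
    col <- 0L
    for (s0 in seq_len(L + 1L)) {
        if (maxIns[s0] > 0L) {
            for (i in seq_len(nu)) {
                ch <- insChars[[i]][[s0]]
                if (length(ch) > 0L)
                    out[i, col + seq_along(ch)] <- ch
            }
            col <- col + maxIns[s0]
        }
        if (s0 <= L) {
            col <- col + 1L
            out[, col] <- alignedAtCenter[, s0]
        }
    }
    rownames(out) <- names(units)
    out
}

#' Call the consensus of an alignment column matrix
#'
#' Per column, the plurality symbol among `{A, C, G, T, -}` is determined
#' (base ties broken in the fixed order A < C < G < T). When the gap is the
#' strict plurality and its frequency reaches `letterConsistency`, the
#' column emits nothing; otherwise the plurality base is emitted. The
#' concatenated emissions form the consensus.
#'
#' @param columns A character matrix as returned by [alignUnits()].
#' @param letterConsistency Column agreement threshold in (0, 1]
#'   (default 0.5).
#' @param readId Identifier stored on the record.
#' @return A [ConsensusRecord-class].
#' @examples
#' m <- alignUnits(rep("ACGTACGT", 5))
#' consensusSequence(callConsensus(m, readId = "r1"))
#' @export
callConsensus <- function(columns, letterConsistency = 0.5,
                          readId = "consensus") {
    stopifnot(is.matrix(columns), nrow(columns) >= 2L,
              letterConsistency > 0, letterConsistency <= 1)
    nu <- nrow(columns)
    symbols <- c(DNA_BASES, "N")
    baseCount <- vapply(symbols, function(b) colSums(columns == b),
                        numeric(ncol(columns)))
    if (ncol(columns) == 1L) baseCount <- matrix(baseCount, nrow = 1L,
                                                 dimnames = list(NULL, symbols))
    gapCount <- colSums(columns == "-")
    topIdx <- apply(baseCount[, DNA_BASES, drop = FALSE], 1L, which.max)
    topBase <- DNA_BASES[topIdx]
    topCount <- baseCount[cbind(seq_along(topBase), topIdx)]
    skip <- gapCount > topCount & gapCount >= letterConsistency * nu

    consChar <- ifelse(skip, "-", topBase)
    seqOut <- paste(consChar[consChar != "-"], collapse = "")
    if (!nzchar(seqOut))
        stop("consensus is empty for read '", readId,
             "' (gap plurality in every column)")
    ident <- rowMeans(columns == matrix(consChar, nrow = nu,
                                        ncol = ncol(columns), byrow = TRUE))
    new("ConsensusRecord", readId = readId, sequence = seqOut,
        nUnits = nu, meanUnitIdentity = mean(ident))
}

#' Consensus straight from repeat units
#'
#' Convenience wrapper: [alignUnits()] followed by [callConsensus()].
#'
#' @inheritParams callConsensus
#' @param units Character vector of repeat-unit sequences.
#' @return A [ConsensusRecord-class].
#' @examples
#' consensusFromUnits(rep(let7aInsert(), 4), readId = "r1")
#' @export
consensusFromUnits <- function(units, letterConsistency = 0.5,
                               readId = "consensus") {
    callConsensus(alignUnits(units), letterConsistency, readId)
}

#' Write consensus records as FASTA
#'
#' Headers carry the unit count and mean unit identity as
#' `read_id n_units=K identity=F`.
#'
#' @param records List of [ConsensusRecord-class] objects.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
writeConsensusFasta <- function(records, path) {
    seqs <- vapply(records, function(r) r@sequence, character(1L))
    hdrs <- vapply(records, function(r)
        sprintf("%s n_units=%d identity=%.4f", r@readId, r@nUnits,
                r@meanUnitIdentity), character(1L))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- hdrs
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}
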