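## K-mer periodicity tandem-repeat detection.
##
## A concatemeric read carries every k-mer of its circular template once per
## rolled-out copy, so template k-mers recur at a spacing equal to the
## template length. Detection therefore (i) finds k-mers that are locally
## frequent (>= peakHeight occurrences inside a sliding window), (ii) splits
## each such k-mer's sorted hit positions wherever consecutive hits are more
## than gapThreshold bases apart, (iii) turns runs of >= peakHeight hits
## into candidate regions extended by margin and clipped to the read, and
## (iv) merges overlapping candidate regions, estimating the period as the
## majority vote across contributing k-mers of the (rounded) median
## inter-hit spacing. The most frequent k-mer inside a merged region becomes
## the segmentation anchor: cutting at its occurrences yields one interval
## per repeat copy, with partial flanking copies shorter than half a period
## discarded.

.kmerVector <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0L))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## window start positions with 50% overlap, always covering the read end
.windowStarts <- function(n, w) {
    lastStart <- max(1L, n - w + 1L)
    unique(c(seq.int(1L, lastStart, by = max(1L, w %/% 2L)), lastStart))
}

## k-mers reaching peakHeight occurrences within at least one window
.candidateKmers <- function(kmers, n, params) {
    k <- params@kmerSize
    w <- params@windowSize
    cand <- character(0L)
    for (st in .windowStarts(n, w)) {
        en <- min(n, st + w - 1L)
        if (en - st + 1L < k) next
        idx <- st:(en - k + 1L)
        tab <- table(kmers[idx])
        cand <- union(cand, names(tab)[tab >= params@peakHeight])
    }
    cand
}

## statistical mode; ties resolved towards the smallest value
.modalValue <- function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
}

#' Detect tandem periodic repeats in a read
#'
#' Scans a read for k-mers that recur periodically and returns one
#' [RepeatAnnotation-class] per detected (merged) periodic region, including
#' the estimated period and the repeat-unit intervals obtained by anchoring
#' on the region's most frequent k-mer. Reads without a periodic region
#' yield an empty list. Detection is strand-symmetric: the reverse
#' complement of a read gives the same period and unit count.
#'
#' A read whose repeat count is below `peakHeight` cannot, by construction,
#' produce the required number of within-window k-mer hits and is reported
#' as repeat-free; at the default `peakHeight = 10` the detector targets
#' reads with at least ten rolled-out copies.
#'
#' @param read A single sequence: character scalar, [Biostrings::DNAString],
#'   or a length-one DNAStringSet element. For sets, see
#'   `lapply(as.character(reads), findPeriodicRegions, params)`.
#' @param params A [RepeatParams-class].
#' @param readId Identifier stored in the annotations (defaults to the
#'   name of `read` if present, else `"read"`).
#' @return A list of [RepeatAnnotation-class] objects (possibly empty).
#' @examples
#' tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' ann <- findPeriodicRegions(strrep(tpl, 25))
#' period(ann[[1]])   # 42
#' nUnits(ann[[1]])
#' @export
findPeriodicRegions <- function(read, params = RepeatParams(),
                                readId = NULL) {
    stopifnot(is(params, "RepeatParams"))
    validObject(params)
    if (is.null(readId))
        readId <- if (!is.null(names(read))) names(read)[1L] else "read"
    s <- asDna(as.character(read))[1L]
    n <- nchar(s)
    k <- params@kmerSize
    if (n < k) return(list())

    kmers <- .kmerVector(s, k)
    cand <- .candidateKmers(kmers, n, params)
    if (length(cand) == 0L) return(list())

    starts <- integer(0L); ends <- integer(0L); periods <- integer(0L)
    for (km in cand) {
        pos <- which(kmers == km)
        runs <- split(pos, cumsum(c(1L, diff(pos) > params@gapThreshold)))
        for (run in runs) {
            if (length(run) < params@peakHeight) next
            sp <- as.integer(round(median(diff(run))))
            if (sp < 1L) next
            starts <- c(starts, max(1L, run[1L] - params@margin))
            ends <- c(ends, min(n, run[length(run)] + k - 1L + params@margin))
            periods <- c(periods, sp)
        }
    }
    if (length(starts) == 0L) return(list())

    ir <- IRanges(starts, ends)
    merged <- reduce(ir)
    out <- vector("list", length(merged))
    for (j in seq_along(merged)) {
        rs <- start(merged)[j]; re <- end(merged)[j]
        member <- start(ir) <= re & end(ir) >= rs
        per <- .modalValue(periods[member])
        out[[j]] <- .annotateRegion(readId, s, kmers, rs, re, per, k)
    }
    out[!vapply(out, is.null, logical(1L))]
}

## build a RepeatAnnotation for one merged region: pick the anchor k-mer and
## cut the region at its occurrences
.annotateRegion <- function(readId, s, kmers, rs, re, period, k) {
    if (re - k + 1L < rs) return(NULL)
    idx <- rs:(re - k + 1L)
    tab <- table(kmers[idx])
    ## anchor = the most frequent k-mer whose occurrence spacing agrees
    ## with the period; a k-mer duplicated *within* the repeat unit (e.g.
    ## insert and adapter sharing a word) has twice the count but an
    ## inconsistent spacing and would cut units at the wrong places
    ord <- order(-as.integer(tab), names(tab))
    anchor <- NULL
    for (km in names(tab)[ord]) {
        ap <- idx[kmers[idx] == km]
        if (length(ap) < 2L) next
        md <- median(diff(ap))
        if (md >= 0.75 * period && md <= 1.25 * period) {
            anchor <- km
            break
        }
    }
    if (is.null(anchor))
        anchor <- names(tab)[ord][1L]
    apos <- idx[kmers[idx] == anchor]
    ## error-created copies of the anchor elsewhere in a unit would cut at
    ## the wrong phase: keep occurrences with at least one period-sized
    ## spacing to a neighbour, then enforce a half-period minimum spacing
    if (length(apos) > 2L) {
        d <- diff(apos)
        dPrev <- c(Inf, d)
        dNext <- c(d, Inf)
        inP <- function(x) x >= 0.75 * period & x <= 1.25 * period
        good <- inP(dPrev) | inP(dNext)
        if (any(good)) apos <- apos[good]
    }
    if (length(apos) > 1L) {
        keep <- rep(TRUE, length(apos))
        last <- apos[1L]
        for (ii in 2L:length(apos)) {
            if (apos[ii] - last < 0.5 * period) keep[ii] <- FALSE
            else last <- apos[ii]
        }
        apos <- apos[keep]
    }

    ustarts <- integer(0L); uends <- integer(0L)
    m <- length(apos)
    if (m >= 2L) {
        ustarts <- apos[-m]
        uends <- apos[-1L] - 1L
        if (apos[1L] - rs >= 0.5 * period) {
            ustarts <- c(rs, ustarts)
            uends <- c(apos[1L] - 1L, uends)
        }
        if (re - apos[m] + 1L >= 0.5 * period) {
            ustarts <- c(ustarts, apos[m])
            uends <- c(uends, re)
        }
    }
    ## an anchor lost to a sequencing error fuses adjacent copies into one
    ## double-length interval; subdivide such intervals at period multiples
    if (length(ustarts) > 0L) {
        fs <- integer(0L); fe <- integer(0L)
        for (ii in seq_along(ustarts)) {
            w <- uends[ii] - ustarts[ii] + 1L
            kparts <- max(1L, as.integer(round(w / period)))
            cuts <- ustarts[ii] + as.integer(round(seq_len(kparts - 1L) *
                                                   w / kparts))
            bs <- c(ustarts[ii], cuts)
            be <- c(cuts - 1L, uends[ii])
            fs <- c(fs, bs); fe <- c(fe, be)
        }
        ustarts <- fs; uends <- fe
    }
    new("RepeatAnnotation", readId = readId, region = IRanges(rs, re),
        period = as.integer(period),
        unitIntervals = IRanges(ustarts, uends), anchor = anchor)
}

#' Extract the repeat-unit subsequences of an annotated read
#'
#' Cuts the read at the annotation's unit intervals (one per repeat copy,
#' anchored on the region's most frequent k-mer). An annotation whose
#' anchor occurred fewer than twice — and which therefore carries no unit
#' intervals — is rejected with an error.
#'
#' @param read The read sequence the annotation was produced from.
#' @param annotation A [RepeatAnnotation-class].
#' @return Character vector of unit subsequences, in read order.
#' @examples
#' tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' read <- strrep(tpl, 10)
#' ann <- findPeriodicRegions(read, RepeatParams(windowSize = 300,
#'                                               peakHeight = 5))[[1]]
#' units <- segmentUnits(read, ann)
#' table(nchar(units))
#' @export
segmentUnits <- function(read, annotation) {
    stopifnot(is(annotation, "RepeatAnnotation"))
    s <- asDna(as.character(read))[1L]
    u <- annotation@unitIntervals
    if (length(u) < 2L)
        stop("annotation rejected: anchor k-mer '", annotation@anchor,
             "' occurs fewer than 2 times in the region of read '",
             annotation@readId, "'")
    if (end(annotation@region) > nchar(s))
        stop("annotation does not fit the supplied read")
    substring(s, start(u), end(u))
}

#' Export repeat annotations as BED
#'
#' Writes one BED line per annotation (0-based, half-open coordinates on
#' the read): columns read id, region start, region end, annotation name,
#' period (column 5), strand (`.`) and unit count (column 7).
#'
#' @param annotations A list of [RepeatAnnotation-class] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
annotationsToBed <- function(annotations, path) {
    rows <- lapply(annotations, function(a) {
        data.frame(chrom = a@readId,
                   start = start(a@region) - 1L,
                   end = end(a@region),
                   name = paste0(a@readId, "_rep"),
                   period = a@period,
                   strand = ".",
                   n_units = length(a@unitIntervals))
    })
    tab <- do.call(rbind, rows)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
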