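#' Build the circular template for an adapter-ligated insert
#'
#' The library molecule is a small RNA ligated to a known adapter and then
#' circularized, so the circular template is the insert followed by the
#' adapter. The linear representation `insert + adapter` is returned; all
#' rotations of it describe the same circle.
#'
#' @param insert Insert sequence (DNA or RNA; `U` is transliterated to `T`).
#' @param adapter Adapter sequence.
#' @return A character scalar of length `nchar(insert) + nchar(adapter)`.
#' @examples
#' tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' nchar(tpl)  # 42, the length of the control oligo
#' @export
buildCircularTemplate <- function(insert, adapter) {
    insert <- .assertNonEmptyDna(insert, "insert")
    adapter <- .assertNonEmptyDna(adapter, "adapter")
    stopifnot(length(insert) == 1L, length(adapter) == 1L)
    paste0(insert, adapter)
}

## Apply the per-base error channel to a clean sequence. Per original base:
## delete with prob delRate, else substitute with prob subRate (to a
## uniformly chosen different base); after each emitted base insert one
## uniformly random base with prob insRate. Consumes the R RNG stream.
.applyErrors <- function(seqchar, subRate, insRate, delRate) {
    if (subRate == 0 && insRate == 0 && delRate == 0)
        return(seqchar)
    b <- strsplit(seqchar, "", fixed = TRUE)[[1L]]
    n <- length(b)
    del <- runif(n) < delRate
    sub <- !del & (runif(n) < subRate)
    if (any(sub)) {
        idx <- match(b[sub], DNA_BASES)
        off <- sample.int(3L, sum(sub), replace = TRUE)
        b[sub] <- DNA_BASES[((idx - 1L + off) %% 4L) + 1L]
    }
    b <- b[!del]
    if (length(b) == 0L) return("")
    ins <- runif(length(b)) < insRate
    if (any(ins))
        b[ins] <- paste0(b[ins], sample(DNA_BASES, sum(ins), replace = TRUE))
    paste(b, collapse = "")
}

.phredString <- function(n, totalRate, jitter) {
    q <- if (totalRate <= 0) 40L else
        as.integer(round(-10 * log10(totalRate)))
    qv <- rep.int(q, n)
    if (jitter > 0L) {
        qv <- qv + sample.int(2L * jitter + 1L, n, replace = TRUE) -
            (jitter + 1L)
        qv <- pmin(pmax(qv, 2L), 41L)
    }
    intToUtf8(qv + 33L)
}

#' Simulate rolling-circle concatemeric nanopore reads
#'
#' Emulates sequencing of rolling-circle reverse-transcription products:
#' for each read a template (insert + adapter circle) is chosen, a tandem
#' repeat count `R` is drawn uniformly from
#' `repeatMin:repeatMax`, the circle is rolled out `R` times starting at a
#' uniformly random phase offset, up to one further template length is
#' truncated from the end (so the first and last copies are typically
#' partial, as in real reads), per-base substitution / insertion / deletion
#' errors are applied, and the read is reverse-complemented with probability
#' `strandFraction`. Phred qualities are constant at the score implied by
#' the total configured error rate (optionally jittered); the FASTQ output
#' is therefore consistent with the error channel.
#'
#' The returned ground truth enables parameter-recovery tests: identical
#' configuration and seed reproduce the output byte for byte.
#'
#' @param config A [SimConfig-class].
#' @return A list with elements `reads` (a
#'   [Biostrings::QualityScaledDNAStringSet] of the simulated reads) and
#'   `truth` (a [S4Vectors::DataFrame] with columns `read_id`,
#'   `template_index`, `repeat_count`, `strand`, `phase_offset`).
#' @examples
#' cfg <- SimConfig(let7aInsert(), nReads = 5, repeatMin = 10,
#'                  repeatMax = 20, seed = 42)
#' sim <- simulateReads(cfg)
#' width(sim$reads)
#' sim$truth
#' @export
simulateReads <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    templates <- vapply(config@insertSequences, function(i)
        buildCircularTemplate(i, config@adapter), character(1L),
        USE.NAMES = FALSE)
    nt <- length(templates)
    totalRate <- config@subRate + config@insRate + config@delRate

    seqs <- character(config@nReads)
    quals <- character(config@nReads)
    ti <- integer(config@nReads)
    rc <- integer(config@nReads)
    strand <- character(config@nReads)
    phase <- integer(config@nReads)

    for (i in seq_len(config@nReads)) {
        ti[i] <- if (nt == 1L) 1L else sample.int(nt, 1L)
        tpl <- templates[ti[i]]
        L <- nchar(tpl)
        rc[i] <- if (config@repeatMin == config@repeatMax) config@repeatMin
                 else sample(config@repeatMin:config@repeatMax, 1L)
        phase[i] <- sample.int(L, 1L) - 1L
        clean <- strrep(rotateSequence(tpl, phase[i]), rc[i])
        trunc <- sample.int(L, 1L) - 1L
        if (trunc > 0L)
            clean <- substr(clean, 1L, nchar(clean) - trunc)
        noisy <- .applyErrors(clean, config@subRate, config@insRate,
                              config@delRate)
        minus <- runif(1L) < config@strandFraction
        strand[i] <- if (minus) "-" else "+"
        if (minus) noisy <- revComp(noisy)
        seqs[i] <- noisy
        quals[i] <- .phredString(nchar(noisy), totalRate,
                                 config@qualityJitter)
    }

    ids <- sprintf("sim_%06d", seq_len(config@nReads))
    keep <- nzchar(seqs)
    reads <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(structure(seqs[keep], names = ids[keep])),
        Biostrings::PhredQuality(quals[keep]))
    truth <- DataFrame(read_id = ids, template_index = ti,
                       repeat_count = rc, strand = strand,
                       phase_offset = phase)[keep, , drop = FALSE]
    list(reads = reads, truth = truth)
}

#' Write simulated reads and their ground truth to disk
#'
#' @param sim The list returned by [simulateReads()].
#' @param fastq Output FASTQ path (Phred+33).
#' @param truthTsv Optional output path for the ground-truth TSV.
#' @return Invisibly, `fastq`.
#' @examples
#' sim <- simulateReads(SimConfig(let7aInsert(), nReads = 3, seed = 1))
#' fq <- tempfile(fileext = ".fastq")
#' writeSimulatedReads(sim, fq)
#' @export
writeSimulatedReads <- function(sim, fastq, truthTsv = NULL) {
    Biostrings::writeQualityScaledXStringSet(sim$reads, fastq)
    if (!is.null(truthTsv))
        write.table(as.data.frame(sim$truth), truthTsv, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(fastq)
}
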