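## End-to-end orchestration: filter -> repeat detection -> unit consensus ->
## rotation phasing / adapter trimming -> optional accuracy scoring and
## equimolar-pool quantification. Stage counts are monotone non-increasing
## and every stage's output can be checkpointed to an output directory.

#' Run the full consensus workflow on a read set
#'
#' Executes, in order: read filtering ([filterReads()]), tandem repeat
#' detection ([findPeriodicRegions()]), unit segmentation and consensus
#' calling ([segmentUnits()], [consensusFromUnits()]), rotation phasing and
#' adapter trimming ([phaseConsensus()]), and optionally accuracy scoring
#' against references ([scoreAccuracy()]) and pool quantification
#' ([mapToPool()], [normalizeCounts()], [biasWithinTwofold()]). Reads
#' failing any stage (no periodic region, too few units, unphaseable) are
#' dropped from later stages; a read with several merged periodic regions
#' contributes one consensus per region.
#'
#' When several references are supplied each insert is scored against all
#' of them and the best (highest percent identity) is reported.
#'
#' @param reads A FASTQ path or a [Biostrings::QualityScaledDNAStringSet].
#' @param adapter Adapter sequence used for rotation phasing.
#' @param filterParams A [FilterParams-class].
#' @param repeatParams A [RepeatParams-class].
#' @param references Optional reference sequence(s) for accuracy scoring:
#'   character vector, DNAStringSet, or FASTA path.
#' @param pool Optional equimolar pool for quantification: named sequences
#'   or FASTA path.
#' @param minRunFrac Unphaseable threshold passed to [phaseConsensus()].
#' @param maxPoolDist Maximum edit distance passed to [mapToPool()].
#' @param outputDir Optional directory for per-stage output files
#'   (filtered FASTQ, annotation BED, consensus FASTA, insert FASTA,
#'   phasing report, accuracy TSV, count TSV, summary TSV).
#' @param verbose One `message()` line per stage (default `TRUE`).
#' @return A list with elements `summary` (a [S4Vectors::DataFrame] of
#'   stage counts), `annotations`, `consensus` (list of
#'   [ConsensusRecord-class]), `phased` (list of [PhasedInsert-class]),
#'   `inserts` (named character vector), `accuracy` (DataFrame or `NULL`)
#'   and `counts` ([CountTable-class] or `NULL`).
#' @examples
#' sim <- simulateReads(SimConfig(let7aInsert(), nReads = 6, repeatMin = 25,
#'                                repeatMax = 30, subRate = 0, insRate = 0,
#'                                delRate = 0, seed = 7))
#' res <- runPipeline(sim$reads, syntheticAdapter(),
#'                    references = let7aInsert(), verbose = FALSE)
#' res$summary
#' @export
runPipeline <- function(reads, adapter,
                        filterParams = FilterParams(),
                        repeatParams = RepeatParams(),
                        references = NULL, pool = NULL,
                        minRunFrac = 0.5, maxPoolDist = 2L,
                        outputDir = NULL, verbose = TRUE) {
    if (is.character(reads))
        reads <- readNanoporeReads(reads)
    adapter <- .assertNonEmptyDna(adapter, "adapter")
    say <- function(...) if (verbose) message(...)
    if (!is.null(outputDir) && !dir.exists(outputDir))
        dir.create(outputDir, recursive = TRUE)
    out <- function(f) if (is.null(outputDir)) NULL else
        file.path(outputDir, f)

    nInput <- length(reads)
    flt <- filterReads(reads, filterParams, verbose = verbose)
    if (!is.null(outputDir) && length(flt) > 0L)
        Biostrings::writeQualityScaledXStringSet(flt, out("filtered.fastq"))

    seqs <- as.character(flt)
    annotations <- list()
    consensus <- list()
    withRepeats <- 0L
    for (rid in names(seqs)) {
        anns <- findPeriodicRegions(seqs[[rid]], repeatParams, readId = rid)
        if (length(anns) == 0L) next
        withRepeats <- withRepeats + 1L
        annotations <- c(annotations, anns)
        for (ai in seq_along(anns)) {
            cid <- if (length(anns) == 1L) rid
                   else paste0(rid, "/", ai)
            rec <- tryCatch({
                units <- segmentUnits(seqs[[rid]], anns[[ai]])
                consensusFromUnits(units,
                                   repeatParams@letterConsistency,
                                   readId = cid)
            }, error = function(e) {
                say("  consensus skipped for ", cid, ": ",
                    conditionMessage(e))
                NULL
            })
            if (!is.null(rec)) consensus[[cid]] <- rec
        }
    }
    say("repeat detection: ", withRepeats, "/", length(flt),
        " reads with periodic repeats; ", length(consensus),
        " consensus sequence(s)")
    if (!is.null(outputDir)) {
        if (length(annotations) > 0L)
            annotationsToBed(annotations, out("annotations.bed"))
        if (length(consensus) > 0L)
            writeConsensusFasta(consensus, out("consensus.fasta"))
    }

    phased <- lapply(consensus, function(rec)
        tryCatch(phaseConsensus(rec, adapter, minRunFrac = minRunFrac),
                 error = function(e) NULL))
    phased <- phased[!vapply(phased, is.null, logical(1L))]
    ok <- vapply(phased, function(p) !p@flagged, logical(1L))
    inserts <- vapply(phased[ok], function(p) p@insert, character(1L))
    say("phasing: ", sum(ok), "/", length(phased),
        " consensus sequences phased")
    if (!is.null(outputDir) && length(phased) > 0L)
        writeInsertsFasta(phased, out("inserts.fasta"),
                          out("phasing_report.tsv"))

    accuracy <- NULL
    if (!is.null(references) && length(inserts) > 0L) {
        refs <- .loadSequences(references)
        accs <- lapply(as.character(refs), function(r)
            scoreAccuracy(inserts, r, ids = names(inserts)))
        accuracy <- accs[[1L]]
        if (length(accs) > 1L) {
            for (a in accs[-1L]) {
                better <- a$percent_identity > accuracy$percent_identity
                accuracy[better, ] <- a[better, ]
            }
        }
        say("accuracy: ", sum(accuracy$percent_identity == 100), "/",
            nrow(accuracy), " inserts at 100% identity")
        if (!is.null(outputDir))
            write.table(as.data.frame(accuracy), out("accuracy.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    counts <- NULL
    if (!is.null(pool) && length(inserts) > 0L) {
        counts <- normalizeCounts(
            mapToPool(inserts, .loadPool(pool), maxDist = maxPoolDist))
        say("quantification: ", counts@totalMapped, " mapped, ",
            counts@unmapped, " unmapped; within 2-fold = ",
            round(biasWithinTwofold(counts), 1), "%")
        if (!is.null(outputDir))
            writeCountTable(counts, out("counts.tsv"))
    }

    summary <- DataFrame(
        stage = c("input", "filtered", "with_repeats", "consensus",
                  "phased"),
        n = c(nInput, length(flt), withRepeats, length(consensus),
              sum(ok)))
    if (!is.null(outputDir))
        write.table(as.data.frame(summary), out("summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)

    list(summary = summary, annotations = annotations,
         consensus = consensus, phased = phased, inserts = inserts,
         accuracy = accuracy, counts = counts)
}

.loadSequences <- function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x))
        x <- Biostrings::readDNAStringSet(x)
    seqs <- asDna(as.character(x), allowN = TRUE)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("ref_%d", seq_along(seqs))
    seqs
}

.loadPool <- function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x))
        x <- Biostrings::readDNAStringSet(x)
    x
}
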