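#' @import methods
#' @importFrom stats median runif
#' @importFrom utils adist head write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce a nucleotide sequence to uppercase DNA
#'
#' RNA inputs (containing `U`) are transliterated to DNA (`T`), matching the
#' cDNA space in which basecalled nanopore reads live. Characters outside
#' `ACGTN` raise an error.
#'
#' @param x A character vector of sequences, or an object coercible to one
#'   (e.g. a [Biostrings::DNAStringSet]).
#' @param allowN Logical; permit `N` (default `TRUE`).
#' @return A character vector of uppercase DNA sequences.
#' @examples
#' asDna("ugagguag")
#' @export
asDna <- function(x, allowN = TRUE) {
    x <- toupper(as.character(x))
    x <- chartr("U", "T", x)
    pat <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
    bad <- !grepl(pat, x)
    if (any(bad))
        stop("sequence contains characters outside the ",
             if (allowN) "ACGTN" else "ACGT", " alphabet: ",
             paste(head(x[bad], 3L), collapse = ", "))
    x
}

.assertNonEmptyDna <- function(x, what = "sequence", allowN = FALSE) {
    x <- asDna(x, allowN = allowN)
    if (length(x) == 0L || any(!nzchar(x)))
        stop(what, " must be a non-empty sequence")
    x
}

#' Reverse complement of a character sequence
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("ACGGT")
#' @export
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a sequence by a fixed offset
#'
#' Returns the cyclic rotation of `x` starting at 0-based position `offset`.
#'
#' @param x A single sequence (character scalar).
#' @param offset Integer 0-based start position, `0 <= offset < nchar(x)`.
#' @return The rotated sequence.
#' @examples
#' rotateSequence("ACGT", 1)  # "CGTA"
#' @export
rotateSequence <- function(x, offset) {
    stopifnot(length(x) == 1L, nzchar(x))
    n <- nchar(x)
    offset <- as.integer(offset) %% n
    if (offset == 0L) return(x)
    paste0(substr(x, offset + 1L, n), substr(x, 1L, offset))
}

# Hard-coded 21-nt control insert: 5' portion of the public miRBase
# hsa-let-7a-5p sequence, in cDNA space.
LET7A_21 <- "TGAGGTAGTAGGTTGTATAGT"

# Synthetic 21-nt adapter used by the simulator, examples and tests. A
# stand-in sequence (the real library adapter is proprietary); chosen to
# share no 5-mer with the let-7a control insert.
SYNTHETIC_ADAPTER_21 <- "CTGCAGGCACCATCAATCAGT"

#' Built-in control sequences
#'
#' `let7aInsert()` returns a 21-nt control insert with the sequence of human
#' miRNA hsa-let-7a (5' 21 nt of the public let-7a-5p sequence, DNA
#' alphabet). `syntheticAdapter()` returns the package's synthetic 21-nt
#' adapter stand-in. Concatenated they form a fully known 42-nt circular
#' template mimicking an adapter-ligated small RNA, convenient for
#' end-to-end accuracy experiments.
#'
#' @return A character scalar.
#' @examples
#' buildCircularTemplate(let7aInsert(), syntheticAdapter())
#' @export
let7aInsert <- function() LET7A_21

#' @rdname let7aInsert
#' @export
syntheticAdapter <- function() SYNTHETIC_ADAPTER_21
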