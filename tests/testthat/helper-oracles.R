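# Shared fixtures and independent oracles, built in code at test time.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# introduce a fixed number of random substitutions / insertions / deletions
mutateSequence <- function(s, nsub = 0, nins = 0, ndel = 0) {
    b <- strsplit(s, "")[[1]]
    if (nsub > 0) {
        pos <- sample(seq_along(b), min(nsub, length(b)))
        for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    }
    if (ndel > 0) {
        pos <- sample(seq_along(b), min(ndel, length(b) - 1))
        b <- b[-pos]
    }
    if (nins > 0) {
        for (k in seq_len(nins)) {
            p <- sample(0:length(b), 1)
            b <- append(b, sample(c("A", "C", "G", "T"), 1), after = p)
        }
    }
    paste(b, collapse = "")
}

# Independent naive local-alignment oracle: plain nested-loop
# Smith-Waterman with affine gaps (match +2, mismatch -3, open -5,
# extend -2; a gap of length g costs 5 + 2g). Best cell is the first
# maximum in a row-major scan; the traceback re-derives each decision from
# the score matrices (diagonal preferred over vertical gap over horizontal
# gap), rather than following stored pointers. Returns the decomposition
# of that optimal alignment into matches, mismatches and gap columns.
oracleLocalAlign <- function(a, b, match = 2, mismatch = -3,
                             gapOpen = 5, gapExt = 2) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    m <- length(av)
    n <- length(bv)
    NEG <- -1e9
    H <- matrix(0, m + 1, n + 1)
    E <- matrix(NEG, m + 1, n + 1)
    F <- matrix(NEG, m + 1, n + 1)
    open <- gapOpen + gapExt
    for (i in 1:m) {
        for (j in 1:n) {
            E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - gapExt)
            F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - gapExt)
            d <- H[i, j] + if (av[i] == bv[j]) match else mismatch
            H[i + 1, j + 1] <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
        }
    }
    best <- 0
    bi <- 0
    bj <- 0
    for (i in seq_len(m + 1)) {
        for (j in seq_len(n + 1)) {
            if (H[i, j] > best) {
                best <- H[i, j]
                bi <- i
                bj <- j
            }
        }
    }
    if (best <= 0)
        return(list(score = 0, alignedBases = 0, editDistance = 0,
                    percentIdentity = 0, flagged = TRUE))
    nM <- 0
    nX <- 0
    nG <- 0
    i <- bi
    j <- bj
    state <- "H"
    while (TRUE) {
        if (state == "H") {
            if (H[i, j] <= 0) break
            d <- if (i > 1 && j > 1)
                H[i - 1, j - 1] +
                    (if (av[i - 1] == bv[j - 1]) match else mismatch)
            else NEG
            if (d == H[i, j]) {
                if (av[i - 1] == bv[j - 1]) nM <- nM + 1 else nX <- nX + 1
                i <- i - 1
                j <- j - 1
            } else if (F[i, j] == H[i, j]) {
                state <- "F"
            } else {
                state <- "E"
            }
        } else if (state == "F") {
            nG <- nG + 1
            fromH <- (H[i - 1, j] - open) >= (F[i - 1, j] - gapExt)
            i <- i - 1
            if (fromH) state <- "H"
        } else {
            nG <- nG + 1
            fromH <- (H[i, j - 1] - open) >= (E[i, j - 1] - gapExt)
            j <- j - 1
            if (fromH) state <- "H"
        }
    }
    ab <- nM + nX + nG
    list(score = best, alignedBases = ab, editDistance = nX + nG,
         percentIdentity = 100 * (ab - (nX + nG)) / ab, flagged = FALSE)
}

# quality-scaled read set with explicit per-base Phred scores
makeQualityRead <- function(bases, quals, id = "r1") {
    stopifnot(nchar(bases) == length(quals))
    x <- Biostrings::DNAStringSet(structure(bases, names = id))
    q <- Biostrings::PhredQuality(intToUtf8(quals + 33L))
    Biostrings::QualityScaledDNAStringSet(x, q)
}
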