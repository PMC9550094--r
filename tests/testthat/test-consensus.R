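test_that("identical units align gap-free and reproduce the unit", {
    for (n in c(2L, 5L, 10L)) {
        m <- alignUnits(rep(let7aInsert(), n))
        expect_identical(dim(m), c(n, 21L))
        expect_false(any(m == "-"))
        rec <- callConsensus(m, readId = "r")
        expect_identical(consensusSequence(rec), let7aInsert())
        expect_identical(nUnits(rec), n)
        expect_equal(rec@meanUnitIdentity, 1)
    }
})

test_that("a one-base deletion produces a single gapped column", {
    m <- alignUnits(c("ACGT", "AGT"))
    expect_identical(dim(m), c(2L, 4L))
    expect_identical(m[1, ], c("A", "C", "G", "T"))
    expect_identical(m[2, ], c("A", "-", "G", "T"))
})

test_that("fewer than two units cannot form a consensus", {
    expect_error(alignUnits("ACGT"), "fewer than 2")
    expect_error(alignUnits(character(0)), "fewer than 2")
})

test_that("alignment length stays within 1.5x the median unit length", {
    set.seed(57)
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    units <- vapply(1:20, function(i) mutateSequence(tpl, nsub = 3, nins = 1,
                                                     ndel = 1), character(1))
    units <- c(units, strrep(tpl, 2))  # doubled unit from a lost anchor
    m <- alignUnits(units)
    expect_lte(ncol(m), 1.5 * median(nchar(units)))
    expect_identical(nrow(m), 20L)     # the doubled unit was excluded
})

test_that("column calling follows the plurality and gap rules", {
    cols <- cbind(c("A", "A", "C", "G"),   # base plurality at threshold
                  c("-", "-", "-", "A"),   # gap plurality above threshold
                  c("A", "A", "C", "C"),   # base tie broken alphabetically
                  c("T", "T", "T", "T"))   # unanimity
    rec <- callConsensus(cols, letterConsistency = 0.5, readId = "r")
    expect_identical(consensusSequence(rec), "AAT")
    # below-threshold plurality base is still emitted
    cols2 <- cbind(c("A", "C", "G", "T"), c("A", "A", "A", "A"))
    expect_identical(consensusSequence(callConsensus(cols2, 0.5, "r")), "AA")
    # gap plurality below threshold emits the plurality base
    cols3 <- cbind(c("-", "-", "A", "C", "G"), c("C", "C", "C", "C", "C"))
    expect_identical(consensusSequence(callConsensus(cols3, 0.75, "r")), "AC")
})

test_that("consensus is invariant to unit order", {
    set.seed(91)
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    units <- vapply(1:15, function(i) mutateSequence(tpl, nsub = 3, nins = 1,
                                                     ndel = 1), character(1))
    c1 <- consensusSequence(consensusFromUnits(units, readId = "r"))
    c2 <- consensusSequence(consensusFromUnits(rev(units), readId = "r"))
    c3 <- consensusSequence(consensusFromUnits(sample(units), readId = "r"))
    expect_identical(c1, c2)
    expect_identical(c1, c3)
})

test_that("consensus identity improves with the number of units at 10% error", {
    set.seed(37)
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    medianIdentity <- function(nu, reps = 40) {
        pid <- vapply(seq_len(reps), function(r) {
            units <- vapply(seq_len(nu), function(i)
                mutateSequence(tpl, nsub = rpois(1, 2.1), nins = rpois(1, 1.05),
                               ndel = rpois(1, 1.05)), character(1))
            cons <- consensusSequence(consensusFromUnits(units, readId = "r"))
            scoreAccuracy(cons, tpl)$percent_identity
        }, numeric(1))
        median(pid)
    }
    meds <- vapply(c(3, 5, 10, 20, 40), medianIdentity, numeric(1))
    expect_true(all(diff(meds) >= 0))
    expect_equal(meds[5], 100)
})
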