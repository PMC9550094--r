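tpl42 <- buildCircularTemplate(let7aInsert(), syntheticAdapter())

test_that("rotation enumeration lists all cyclic shifts in offset order", {
    expect_identical(enumerateRotations("ACG"), c("ACG", "CGA", "GAC"))
    expect_identical(enumerateRotations("AAAA"), rep("AAAA", 4))
    expect_length(enumerateRotations(tpl42), 42L)
    expect_error(enumerateRotations(""), "non-empty")
})

test_that("phasing recovers the exact insert from any rotation and strand", {
    set.seed(83)
    for (case in 1:200) {
        insert <- randomDna(sample(15:60, 1))
        adapter <- randomDna(sample(15:40, 1))
        cons <- rotateSequence(buildCircularTemplate(insert, adapter),
                               sample(0:(nchar(insert) + nchar(adapter) - 1), 1))
        minus <- runif(1) < 0.5
        if (minus) cons <- revComp(cons)
        ph <- phaseConsensus(cons, adapter)
        expect_false(isUnphaseable(ph))
        expect_identical(insertSequence(ph), insert)
        expect_identical(ph@strand, if (minus) "-" else "+")
    }
})

test_that("phasing is invariant to the starting rotation", {
    inserts <- vapply(c(0, 5, 17, 33, 41), function(o)
        insertSequence(phaseConsensus(rotateSequence(tpl42, o),
                                      syntheticAdapter())), character(1))
    expect_identical(unique(inserts), let7aInsert())
})

test_that("reverse-complementing the consensus flips strand, same insert", {
    ph <- phaseConsensus(rotateSequence(tpl42, 13), syntheticAdapter())
    phrc <- phaseConsensus(revComp(rotateSequence(tpl42, 13)),
                           syntheticAdapter())
    expect_identical(insertSequence(ph), insertSequence(phrc))
    expect_false(ph@strand == phrc@strand)
})

test_that("adapter-free and adapter-only consensus sequences are flagged", {
    set.seed(59)
    ph <- phaseConsensus(randomDna(42), syntheticAdapter())
    expect_true(isUnphaseable(ph))
    expect_warning(
        phA <- phaseConsensus(syntheticAdapter(), syntheticAdapter()),
        "empty insert")
    expect_true(isUnphaseable(phA))
    expect_identical(insertSequence(phA), "")
    expect_error(trimAdapter(phA), "unphaseable")
})

test_that("adapter trimming removes exactly the adapter interval", {
    ph <- phaseConsensus(rotateSequence(tpl42, 10), syntheticAdapter())
    ins <- trimAdapter(ph)
    expect_identical(ins, let7aInsert())
    expect_identical(nchar(ins),
                     nchar(tpl42) - IRanges::width(ph@adapterInterval))
    expect_identical(ins, insertSequence(ph))
    expect_lte(ph@ungappedAlignmentLength, nchar(syntheticAdapter()))
})

test_that("error-free simulated batches phase to their true inserts", {
    cfg <- SimConfig(c(let7aInsert(), randomDna(25), randomDna(30)),
                     syntheticAdapter(), repeatMin = 12, repeatMax = 20,
                     nReads = 30, subRate = 0, insRate = 0, delRate = 0,
                     seed = 67)
    set.seed(67)
    sim <- simulateReads(cfg)
    for (i in seq_along(sim$reads)) {
        s <- as.character(sim$reads[[i]])
        ann <- findPeriodicRegions(s)
        if (length(ann) == 0) next
        units <- segmentUnits(s, ann[[1]])
        rec <- consensusFromUnits(units, readId = "r")
        ph <- phaseConsensus(rec, syntheticAdapter())
        expect_identical(insertSequence(ph),
                         cfg@insertSequences[sim$truth$template_index[i]])
    }
})
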