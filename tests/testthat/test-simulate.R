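test_that("circular template construction concatenates insert and adapter", {
    expect_identical(buildCircularTemplate(strrep("A", 21), strrep("C", 21)),
                     paste0(strrep("A", 21), strrep("C", 21)))
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    expect_identical(nchar(tpl), 42L)  # the 42-mer control oligo layout
    expect_identical(buildCircularTemplate("UGAGGUAGUAGGUUGUAUAGU",
                                           syntheticAdapter()),
                     buildCircularTemplate(let7aInsert(), syntheticAdapter()))
    expect_error(buildCircularTemplate("", "ACGT"), "non-empty")
    expect_error(buildCircularTemplate("ACXT", "ACGT"), "alphabet")
})

test_that("error-free reads are perfect rolled-out templates", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), repeatMin = 3,
                     repeatMax = 8, nReads = 25, subRate = 0, insRate = 0,
                     delRate = 0, seed = 3)
    sim <- simulateReads(cfg)
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    L <- nchar(tpl)
    for (i in seq_along(sim$reads)) {
        tr <- sim$truth[i, ]
        s <- as.character(sim$reads[[i]])
        if (tr$strand == "-") s <- revComp(s)
        full <- strrep(rotateSequence(tpl, tr$phase_offset), tr$repeat_count)
        expect_identical(s, substr(full, 1L, nchar(s)))
        expect_gt(nchar(s), (tr$repeat_count - 1L) * L)
        expect_lte(nchar(s), tr$repeat_count * L)
    }
})

test_that("identical seed and config give byte-identical output", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), nReads = 20,
                     repeatMin = 5, repeatMax = 15, seed = 7)
    f1 <- tempfile(fileext = ".fastq")
    f2 <- tempfile(fileext = ".fastq")
    writeSimulatedReads(simulateReads(cfg), f1)
    writeSimulatedReads(simulateReads(cfg), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_true(any(nzchar(readLines(f1))))
})

test_that("observed substitution divergence matches the configured rate", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), repeatMin = 20,
                     repeatMax = 20, nReads = 500, subRate = 0.1,
                     insRate = 0, delRate = 0, strandFraction = 0, seed = 19)
    sim <- simulateReads(cfg)
    tpl <- buildCircularTemplate(let7aInsert(), syntheticAdapter())
    div <- vapply(seq_along(sim$reads), function(i) {
        s <- as.character(sim$reads[[i]])
        clean <- substr(strrep(rotateSequence(tpl, sim$truth$phase_offset[i]),
                               20L), 1L, nchar(s))
        a <- strsplit(s, "")[[1]]
        b <- strsplit(clean, "")[[1]]
        mean(a != b)
    }, numeric(1))
    expect_lt(abs(mean(div) - 0.10), 0.01)
})

test_that("emitted qualities imply the configured total error rate", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), nReads = 10,
                     repeatMin = 10, repeatMax = 10, subRate = 0.04,
                     insRate = 0.02, delRate = 0.02, seed = 5)
    sim <- simulateReads(cfg)
    impliedErr <- 10^(-meanQuality(sim$reads) / 10)
    expect_true(all(abs(impliedErr - 0.08) / 0.08 <= 0.2))
})

test_that("read length correlates with true repeat count", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), repeatMin = 5,
                     repeatMax = 50, nReads = 200, subRate = 0.04,
                     insRate = 0.02, delRate = 0.02, seed = 23)
    sim <- simulateReads(cfg)
    rho <- cor(Biostrings::width(sim$reads), sim$truth$repeat_count,
               method = "spearman")
    expect_gt(rho, 0.95)
})

test_that("invalid simulator configurations are rejected", {
    expect_error(SimConfig(let7aInsert(), nReads = 0), "nReads")
    expect_error(SimConfig(let7aInsert(), subRate = 0.3, insRate = 0.2,
                           delRate = 0.1), "rates")
    expect_error(SimConfig(let7aInsert(), subRate = -0.1), "rates")
    expect_error(SimConfig("ACGT"), "insert lengths")
    expect_error(SimConfig(let7aInsert(), repeatMin = 0), "repeatMin")
})
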