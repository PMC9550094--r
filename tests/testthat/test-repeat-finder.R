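tpl42 <- buildCircularTemplate(let7aInsert(), syntheticAdapter())

test_that("an error-free concatemer yields one full-span annotation", {
    read <- strrep(tpl42, 25)
    anns <- findPeriodicRegions(read)
    expect_length(anns, 1)
    ann <- anns[[1]]
    expect_identical(period(ann), 42L)
    expect_gte(IRanges::width(repeatRegion(ann)) / nchar(read), 0.95)
    expect_true(nUnits(ann) >= 24 && nUnits(ann) <= 26)
})

test_that("random sequence yields no annotation at default parameters", {
    set.seed(101)
    expect_length(findPeriodicRegions(randomDna(1050)), 0)
    # false-positive rate over many random reads
    hits <- sum(vapply(1:300, function(i)
        length(findPeriodicRegions(randomDna(1050))) > 0, logical(1)))
    expect_lt(hits / 300, 0.01)
})

test_that("period survives 10% sequencing error within +-2", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), repeatMin = 25,
                     repeatMax = 25, nReads = 10, subRate = 0.05,
                     insRate = 0.025, delRate = 0.025, strandFraction = 0,
                     seed = 13)
    sim <- simulateReads(cfg)
    for (i in seq_along(sim$reads)) {
        anns <- findPeriodicRegions(as.character(sim$reads[[i]]))
        expect_gte(length(anns), 1)
        expect_lte(abs(period(anns[[1]]) - 42L), 2L)
    }
})

test_that("detection is strand-symmetric", {
    read <- strrep(tpl42, 20)
    fwd <- findPeriodicRegions(read)[[1]]
    rev <- findPeriodicRegions(revComp(read))[[1]]
    expect_identical(period(fwd), period(rev))
    expect_identical(nUnits(fwd), nUnits(rev))
})

test_that("error-free period equals template length for arbitrary templates", {
    set.seed(71)
    for (rep in 1:20) {
        L <- sample(20:100, 1)
        tpl <- randomDna(L)
        R <- sample(12:30, 1)
        phase <- sample(0:(L - 1), 1)
        read <- strrep(rotateSequence(tpl, phase), R)
        anns <- findPeriodicRegions(read)
        expect_length(anns, 1)
        expect_identical(period(anns[[1]]), L)
        expect_lte(abs(nUnits(anns[[1]]) - R), 1L)
    }
})

test_that("unit segmentation returns identical full-length units on clean data", {
    read <- strrep(tpl42, 12)
    ann <- findPeriodicRegions(read)[[1]]
    units <- segmentUnits(read, ann)
    expect_true(length(units) %in% 11:13)
    full <- units[nchar(units) == 42]
    expect_gte(length(full), 11)
    expect_length(unique(full), 1L)
    # all units are rotations of the template
    expect_true(all(vapply(full, function(u)
        grepl(u, strrep(tpl42, 2), fixed = TRUE), logical(1))))
})

test_that("unit lengths stay near the period under 10% error", {
    cfg <- SimConfig(let7aInsert(), syntheticAdapter(), repeatMin = 30,
                     repeatMax = 30, nReads = 5, subRate = 0.05,
                     insRate = 0.025, delRate = 0.025, strandFraction = 0,
                     seed = 29)
    sim <- simulateReads(cfg)
    lens <- unlist(lapply(seq_along(sim$reads), function(i) {
        s <- as.character(sim$reads[[i]])
        ann <- findPeriodicRegions(s)[[1]]
        nchar(segmentUnits(s, ann))
    }))
    expect_gte(mean(abs(lens - 42) <= 5), 0.9)
})

test_that("annotations without a usable anchor are rejected", {
    ann <- new("RepeatAnnotation", readId = "r", region = IRanges::IRanges(1, 100),
               period = 42L, unitIntervals = IRanges::IRanges(), anchor = "ACGTA")
    expect_error(segmentUnits(randomDna(100), ann), "fewer than 2")
})

test_that("BED export carries period and unit count in columns 5 and 7", {
    read <- strrep(tpl42, 15)
    anns <- findPeriodicRegions(read, readId = "read1")
    bed <- tempfile(fileext = ".bed")
    annotationsToBed(anns, bed)
    tab <- read.delim(bed, header = FALSE)
    expect_identical(tab$V1, "read1")
    expect_identical(tab$V2, 0L)             # 0-based start
    expect_identical(tab$V3, nchar(read))    # half-open end
    expect_identical(tab$V5, 42L)
    expect_identical(tab$V7, nUnits(anns[[1]]))
})
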