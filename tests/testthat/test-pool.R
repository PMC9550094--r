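smallPool <- c(mirA = "ACGTACGTACGTACGTACGT",
               mirB = "TTTTGGGGCCCCAAAATTTT",
               mirC = "GACTGACTGACTGACTGACT")

test_that("exact and near matches are assigned, ambiguous ones are not", {
    ct <- mapToPool(c(smallPool[["mirA"]],                # exact
                      "TTTTGGGGCCCCAAAATTAT",             # 1 edit from mirB
                      "GGGGGGGGGGGGGGGGGGGG"),            # far from all
                    smallPool)
    counts <- poolCounts(ct)
    expect_identical(counts$raw_count[counts$reference_id == "mirA"], 1L)
    expect_identical(counts$raw_count[counts$reference_id == "mirB"], 1L)
    expect_identical(ct@unmapped, 1L)
    expect_identical(ct@totalMapped, 2L)
})

test_that("inserts equidistant from two members stay unmapped", {
    pool <- c(a = "AAAAAAAACC", b = "AAAAAAAAGG")
    # one edit from both members
    ct <- mapToPool("AAAAAAAACG", pool)
    expect_identical(ct@totalMapped, 0L)
    expect_identical(ct@unmapped, 1L)
})

test_that("an error-free one-read-per-member library maps perfectly", {
    set.seed(149)
    pool <- character(962)
    repeat {
        pool <- vapply(1:962, function(i) randomDna(sample(18:26, 1)),
                       character(1))
        if (!anyDuplicated(pool)) break
    }
    names(pool) <- sprintf("mir%04d", 1:962)
    ct <- mapToPool(sample(unname(pool)), pool)
    expect_identical(ct@unmapped, 0L)
    expect_true(all(poolCounts(ct)$raw_count == 1L))
    nct <- normalizeCounts(ct)
    expect_true(all(poolCounts(nct)$normalized_count == 1))
    expect_equal(biasWithinTwofold(nct), 100)
})

test_that("normalization divides by the expected per-member count", {
    raw <- structure(rep(10L, 962), names = sprintf("m%03d", 1:962))
    raw[5] <- 20L
    raw[6] <- 0L
    ct <- normalizeCounts(countTable(raw))
    nv <- poolCounts(ct)$normalized_count
    expected <- sum(raw) / 962
    expect_equal(nv[5], 20 / expected)
    expect_equal(nv[6], 0)
    expect_equal(nv[1], 10 / expected)
    # worked example: total 9620 over 962 members, raw 20 -> 2.0
    ct2 <- normalizeCounts(countTable(structure(
        c(20L, rep(10L, 960), 0L), names = sprintf("x%03d", 1:962))))
    expect_equal(poolCounts(ct2)$normalized_count[1], 20 / (9620 / 962))
    expect_error(normalizeCounts(countTable(structure(integer(3),
        names = c("a", "b", "c")))), "no mapped reads")
})

test_that("mean normalized count is 1 when every member is counted", {
    set.seed(151)
    raw <- structure(rpois(500, 8) + 1L, names = sprintf("m%03d", 1:500))
    ct <- normalizeCounts(countTable(raw))
    expect_equal(mean(poolCounts(ct)$normalized_count), 1)
})

test_that("the within-2-fold metric uses a closed interval and is scale-free", {
    # normalized values exactly {0.5, 2, 0.5, 1}: all inside the interval
    raw <- structure(c(2L, 8L, 2L, 4L), names = c("a", "b", "c", "d"))
    expect_equal(biasWithinTwofold(countTable(raw)), 100)
    # rescaling all raw counts leaves the metric unchanged
    set.seed(157)
    raw2 <- structure(rpois(200, 3), names = sprintf("m%03d", 1:200))
    expect_equal(biasWithinTwofold(countTable(raw2)),
                 biasWithinTwofold(countTable(raw2 * 7L)))
    # gross skew: half heavily over-, half under-represented
    skew <- structure(c(rep(40L, 50), rep(0L, 150)),
                      names = sprintf("s%03d", 1:200))
    expect_equal(biasWithinTwofold(countTable(skew)), 0)
})

test_that("count tables round-trip through TSV", {
    ct <- normalizeCounts(countTable(structure(c(3L, 7L), names = c("a", "b"))))
    tsv <- tempfile(fileext = ".tsv")
    writeCountTable(ct, tsv)
    back <- readCountTable(tsv)
    expect_identical(poolCounts(back)$raw_count, poolCounts(ct)$raw_count)
    expect_identical(back@poolSize, 2L)
})
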