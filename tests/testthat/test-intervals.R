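test_that("overlapBp follows half-open interval arithmetic", {
    expect_equal(overlapBp(bedRanges("chr1", 0, 100),
                           bedRanges("chr1", 50, 150)), 50)
    # half-open abutment shares no base
    expect_equal(overlapBp(bedRanges("chr1", 0, 100),
                           bedRanges("chr1", 100, 200)), 0)
    expect_equal(overlapBp(bedRanges("chr1", 0, 100),
                           bedRanges("chr2", 0, 100)), 0)
})

test_that("overlapFraction honours its designated denominator", {
    a <- bedRanges("chr1", 0, 100); b <- bedRanges("chr1", 50, 150)
    expect_equal(overlapFraction(a, b, "of_a"), 0.5)
    expect_equal(overlapFraction(a, a, "of_a"), 1.0)
    expect_equal(overlapFraction(a, a, "of_b"), 1.0)
    expect_equal(overlapFraction(a, a, "of_smaller"), 1.0)
    # contained narrow interval is fully overlapped
    expect_equal(overlapFraction(bedRanges("chr1", 0, 1000),
                                 bedRanges("chr1", 900, 950), "of_b"), 1.0)
    expect_error(overlapFraction(a, b), "of_a|denominator|arg")
})

test_that("mergeByFraction merges qualifying pairs and leaves others", {
    m <- mergeByFraction(bedRanges("chr1", c(0, 60), c(100, 160)), 0.25)
    expect_equal(bedCoords(m)[, c("start", "end")],
                 data.frame(start = 0, end = 160))
    # 20 bp overlap is 0.20 of one and ~0.167 of the other: no merge
    m2 <- mergeByFraction(bedRanges("chr1", c(0, 80), c(100, 200)), 0.25)
    expect_equal(nrow(bedCoords(m2)), 2L)
    expect_equal(bedCoords(m2)$start, c(0, 80))
    # singleton fixpoint
    m3 <- mergeByFraction(bedRanges("chr1", 0, 100), 0.5)
    expect_equal(bedCoords(m3)$end, 100)
    expect_error(mergeByFraction(bedRanges("chr1", 0, 100), 0), "minFrac")
})

test_that("merge output is an order-independent idempotent fixpoint", {
    set.seed(101)
    for (rep in 1:10) {
        gr <- randomIntervals(40, maxCoord = 5000)
        minFrac <- sample(c(0.1, 0.25, 0.5, 1), 1)
        out <- mergeByFraction(gr, minFrac)
        expect_true(oracleMergeIsFixpoint(gr, out, minFrac))
        # idempotent
        expect_identical(bedCoords(mergeByFraction(out, minFrac)),
                         bedCoords(out))
        # order-independent
        shuf <- gr[sample(length(gr))]
        expect_identical(bedCoords(mergeByFraction(shuf, minFrac)),
                         bedCoords(out))
    }
})

test_that("interval operations agree with per-base set oracles", {
    set.seed(202)
    for (rep in 1:200) {
        ab <- randomIntervals(2, maxCoord = 2000, maxWidth = 300)
        a <- ab[1]; b <- ab[2]
        ov <- overlapBp(a, b)
        expect_identical(ov, as.integer(oracleOverlapBp(a, b)))
        expect_identical(ov, overlapBp(b, a))  # symmetric
        expect_lte(ov, min(GenomicRanges::width(a), GenomicRanges::width(b)))
        fr <- overlapFraction(a, b, "of_smaller")
        expect_gte(fr, 0); expect_lte(fr, 1)
    }
    for (rep in 1:50) {
        region <- randomIntervals(1, maxCoord = 1500, maxWidth = 500)
        blocks <- randomIntervals(sample(0:6, 1), maxCoord = 1500,
                                  chroms = "chr1")
        cf <- coverageFraction(region, blocks)
        expect_equal(cf, oracleCoverageFraction(region, blocks))
        expect_gte(cf, 0); expect_lte(cf, 1)
    }
})

test_that("coverageFraction counts overlapping blocks once and survives block splitting", {
    region <- bedRanges("chr1", 0, 1000)
    expect_equal(coverageFraction(region,
        bedRanges("chr1", c(0, 500), c(400, 900))), 0.8)
    expect_equal(coverageFraction(region, GenomicRanges::GRanges()), 0)
    # overlapping blocks cover every base exactly once
    expect_equal(coverageFraction(region,
        bedRanges("chr1", c(0, 400), c(600, 1000))), 1.0)
    # splitting a block into abutting sub-blocks changes nothing
    whole <- bedRanges("chr1", 100, 700)
    split3 <- bedRanges("chr1", c(100, 300, 500), c(300, 500, 700))
    expect_equal(coverageFraction(region, whole),
                 coverageFraction(region, split3))
})

test_that("nearestPointDistance uses midpoints with a lower-position tie-break", {
    r <- bedRanges("chr1", 69500, 70500)
    nd <- nearestPointDistance(r, data.frame(chrom = "chr1", pos = 10000))
    expect_equal(nd$distance, 60000)
    # point at the midpoint itself
    expect_equal(nearestPointDistance(bedRanges("chr1", 100, 200),
        data.frame(chrom = "chr1", pos = 150))$distance, 0)
    # equidistant points: lower position wins
    tie <- nearestPointDistance(bedRanges("chr1", 900, 1100),
        data.frame(chrom = "chr1", pos = c(900, 1100),
                   gene_id = c("lo", "hi")))
    expect_equal(tie$gene_id, "lo")
    # no same-chromosome point is an explicit error, never a silent zero
    expect_error(nearestPointDistance(bedRanges("chr1", 0, 100),
        data.frame(chrom = "chr2", pos = 50)), "chromosome")
    na <- nearestPointDistance(bedRanges("chr1", 0, 100),
        data.frame(chrom = "chr2", pos = 50), onMissing = "na")
    expect_true(is.na(na$distance))
})

test_that("zero-width and invalid intervals are rejected at construction", {
    expect_error(bedRanges("chr1", 100, 100), "zero-width|end")
    expect_error(bedRanges("chr1", 200, 100), "end")
    expect_error(bedRanges("chr1", -5, 100), "start")
})
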