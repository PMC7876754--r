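test_that("the five-state rule matches a hand-written predicate over the whole count cube", {
    grid <- expand.grid(n1 = 0:4, n2 = 0:4, n3 = 0:4)
    got <- classifyRegion(grid$n1, grid$n2, grid$n3)
    want <- mapply(oracleClassify4, grid$n1, grid$n2, grid$n3)
    expect_identical(as.character(got), unname(want))
    # exactly one state everywhere; the five named predicates are disjoint
    expect_false(anyNA(got))
    # the published worked cases
    expect_equal(as.character(classifyRegion(4, 3, 0)), "active")
    expect_equal(as.character(classifyRegion(3, 0, 3)), "bivalent")
    expect_equal(as.character(classifyRegion(4, 0, 0)), "h3k4me1_only")
    expect_equal(as.character(classifyRegion(3, 1, 0)), "unclassified")
    expect_equal(as.character(classifyRegion(0, 0, 0)), "unclassified")
    # active and bivalent are disjoint by construction
    expect_false(any(got == "active" & grid$n3 > 0))
    expect_false(any(got == "bivalent" & grid$n2 > 0))
})

test_that("classifyRegion validates its configuration", {
    expect_error(classifyRegion(1, 1, 1, presenceMin = 2, absenceMax = 2),
                 "absenceMax")
    expect_error(classifyRegion(1, 1, 1, totals = c(H3K4me1 = 2, H3K27ac = 4,
                                                    H3K27me3 = 4)),
                 "presenceMin")
    expect_error(classifyRegion(5, 0, 0), "exceed")
})

test_that("reference building merges pooled H3K4me1 peaks only", {
    es1 <- PeakSet(bedRanges("chr1", 0, 100), "s1", "H3K4me1")
    es2 <- PeakSet(bedRanges("chr1", 0, 100), "s2", "H3K4me1")
    tis <- PeakSet(bedRanges("chr1", 60, 160), "t1", "H3K4me1", "pool")
    ac <- PeakSet(bedRanges("chr1", 5000, 6000), "s1", "H3K27ac")
    # identical peaks collapse to one region
    expect_equal(nrow(bedCoords(buildReferenceRegions(list(es1, es2)))), 1L)
    # ES + tissue peak merge across contexts; H3K27ac never seeds rows
    ref <- buildReferenceRegions(list(es1, tis, ac))
    expect_equal(bedCoords(ref)[, c("start", "end")],
                 data.frame(start = 0, end = 160))
    # disjoint chromosomes stay apart
    two <- buildReferenceRegions(list(
        PeakSet(bedRanges(c("chr1", "chr2"), c(0, 0), c(100, 100)),
                "s1", "H3K4me1")))
    expect_equal(length(two), 2L)
    expect_error(buildReferenceRegions(list(ac)), "H3K4me1")
})

test_that("promoter filtering removes any region touching a 1 kb TSS window", {
    gm <- geneModelsFromFrame(data.frame(
        gene_id = "g", chrom = "chr1", tss = 1000, strand = "+",
        tx_start = 1000, tx_end = 5000, exon_starts = "", exon_ends = "",
        stringsAsFactors = FALSE))
    reg <- bedRanges("chr1", c(900, 2000, 1499), c(1100, 3000, 1600))
    kept <- suppressMessages(filterPromoterRegions(reg, gm, 500))
    # direct hit and the 1 bp boundary overlap are removed; distal survives
    expect_equal(bedCoords(kept)$start, 2000)
    expect_equal(S4Vectors::metadata(kept)$n_removed, 2L)
})

test_that("presence matrix applies the inclusive 25%-of-region rule", {
    regions <- bedRanges("chr1", 0, 1000)
    ps <- function(s, e) PeakSet(bedRanges("chr1", s, e), "s1", "H3K4me1")
    at <- buildPresenceMatrix(regions, list(ps(0, 250)), 0.25)
    expect_equal(as.integer(SummarizedExperiment::assay(at, "presence")), 1L)
    below <- buildPresenceMatrix(regions, list(ps(0, 249)), 0.25)
    expect_equal(as.integer(SummarizedExperiment::assay(below, "presence")), 0L)
    none <- buildPresenceMatrix(regions,
        list(PeakSet(bedRanges("chr2", 0, 1000), "s1", "H3K4me1")), 0.25)
    expect_equal(as.integer(SummarizedExperiment::assay(none, "presence")), 0L)
    # two peaks hitting one region still give a single 1
    multi <- buildPresenceMatrix(regions,
        list(ps(c(0, 500), c(400, 900))), 0.25)
    expect_equal(as.integer(SummarizedExperiment::assay(multi, "presence")), 1L)
})

test_that("classifyStates composes row-wise and is order-invariant", {
    # five regions engineered to the canonical count rows
    regions <- bedRanges("chr1", (0:4) * 10000, (0:4) * 10000 + 1000)
    wanted <- list(c(4, 3, 0), c(3, 0, 3), c(4, 0, 0), c(3, 1, 0),
                   c(0, 0, 0))
    psets <- list()
    for (m in 1:3) for (s in 1:4) {
        idx <- which(vapply(wanted, `[[`, 0, m) >= s)
        gr <- if (length(idx))
            bedRanges("chr1", (idx - 1) * 10000, (idx - 1) * 10000 + 1000)
        else GenomicRanges::GRanges()
        psets[[length(psets) + 1L]] <-
            PeakSet(gr, paste0("ES_s", s), MARK_LEVELS[m])
    }
    es <- classifyStates(buildPresenceMatrix(regions, psets, 0.25))
    sc <- stateCounts(es)
    expect_equal(sc[["active"]], 1L)
    expect_equal(sc[["bivalent"]], 1L)
    expect_equal(sc[["h3k4me1_only"]], 1L)
    expect_equal(sc[["unclassified"]], 2L)
    expect_equal(sum(sc), length(regions))
    # permuting samples and regions changes nothing
    es2 <- classifyStates(buildPresenceMatrix(
        rev(regions), rev(psets), 0.25))
    expect_equal(stateCounts(es2), sc)
    expect_identical(as.character(rev(stateCalls(es2))),
                     as.character(stateCalls(es)))
    # an all-zero matrix is entirely unclassified
    far <- buildPresenceMatrix(bedRanges("chr2", c(0, 5000), c(1000, 6000)),
                               psets, 0.25)
    expect_equal(stateCounts(classifyStates(far))[["unclassified"]], 2L)
})

test_that("presenceCurve is a monotone recount of per-region sample support", {
    pk <- bedRanges("chr1", (0:9) * 5000, (0:9) * 5000 + 1000)
    same4 <- lapply(1:4, function(s) PeakSet(pk, paste0("s", s), "H3K4me1"))
    expect_equal(unname(presenceCurve(same4)), c(10L, 10L, 10L, 10L))
    # peaks private to one sample each
    solo <- lapply(1:4, function(s)
        PeakSet(bedRanges("chr1", s * 40000, s * 40000 + 1000),
                paste0("s", s), "H3K4me1"))
    expect_equal(unname(presenceCurve(solo)), c(4L, 0L, 0L, 0L))
    # random instance: recount by brute force
    set.seed(31)
    rnd <- lapply(1:4, function(s)
        PeakSet(randomIntervals(30, maxCoord = 50000, maxWidth = 800),
                paste0("s", s), "H3K4me1"))
    curve <- presenceCurve(rnd)
    regions <- mergeByFraction(unlist(methods::as(lapply(rnd, peaks),
                                                  "GRangesList")), 0.25)
    support <- vapply(seq_along(regions), function(i) {
        sum(vapply(rnd, function(ps) {
            any(overlapFraction(rep(regions[i], length(peaks(ps))),
                                peaks(ps), "of_a") >= 0.25)
        }, TRUE))
    }, 0L)
    expect_equal(unname(curve), vapply(1:4, function(N)
        sum(support >= N), 0L))
    expect_true(all(diff(curve) <= 0))
    expect_error(presenceCurve(list(same4[[1]],
        PeakSet(pk, "x", "H3K27ac"))), "single mark")
})
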