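test_that("occupancy takes the strict >50%-of-the-factor-peak rule", {
    region <- bedRanges("chr1", 0, 1000)
    # peak fully inside the region
    expect_true(occupancy(region, bedRanges("chr1", 100, 300)))
    # 100 of 400 bases inside: 0.25, not bound
    expect_false(occupancy(region, bedRanges("chr1", 900, 1300)))
    # exactly half inside is NOT bound (strict >)
    expect_false(occupancy(region, bedRanges("chr1", 800, 1200)))
    expect_true(occupancy(region, bedRanges("chr1", 800, 1200),
                          occupancyFrac = 0.49))
    # the alternative denominator reads the fraction off the region
    expect_false(occupancy(region, bedRanges("chr1", 100, 300),
                           denominator = "region"))
    expect_true(occupancy(region, bedRanges("chr1", 0, 600),
                          denominator = "region"))
    expect_equal(occupancy(region, GenomicRanges::GRanges()), FALSE)
})

test_that("factor counts equal a brute-force double loop", {
    region <- bedRanges("chr1", 0, 1000)
    five <- lapply(1:5, function(i)
        bedRanges("chr1", 100 * i, 100 * i + 150))
    names(five) <- paste0("f", 1:5)
    three <- five
    three$f4 <- bedRanges("chr2", 0, 200)
    three$f5 <- bedRanges("chr1", 5000, 5200)
    expect_equal(factorCountPerRegion(region, three), 3L)
    expect_equal(factorCountPerRegion(region,
        list(a = GenomicRanges::GRanges())), 0L)
    set.seed(13)
    regions <- randomIntervals(40, maxCoord = 8000, maxWidth = 600)
    fps <- lapply(1:6, function(i)
        randomIntervals(15, maxCoord = 8000, maxWidth = 250))
    names(fps) <- paste0("f", 1:6)
    got <- factorCountPerRegion(regions, fps)
    brute <- vapply(seq_along(regions), function(r)
        sum(vapply(fps, function(fp) {
            any(vapply(seq_along(fp), function(j)
                oracleOverlapBp(regions[r], fp[j]) >
                    0.5 * GenomicRanges::width(fp[j]), TRUE))
        }, TRUE)), 0L)
    expect_equal(got, brute)
})

test_that("hypergeomTail is exact against exhaustive enumeration", {
    expect_equal(hypergeomTail(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
    expect_equal(hypergeomTail(0, 4, 5, 10), 1.0)
    expect_equal(hypergeomTail(6, 6, 6, 6), 1.0)  # forced draw
    for (N in c(5L, 8L)) for (K in 0:N) for (n in 0:N)
        for (k in 0:min(K, n))
            expect_equal(hypergeomTail(k, K, n, N),
                         oracleHyperTail(k, K, n, N), tolerance = 1e-10)
    # non-increasing in k
    p <- hypergeomTail(0:4, 4, 6, 12)
    expect_true(all(diff(p) <= 1e-12))
    expect_error(hypergeomTail(5, 4, 5, 10), "invalid")
    expect_error(hypergeomTail(1, 4, 11, 10), "invalid")
})

test_that("factor enrichment flags planted preferences and respects Bonferroni", {
    # 1000 regions in 5 states; one factor binding 50/100 of state-a
    # regions vs 50/1000 overall is overwhelmingly enriched
    regions <- bedRanges("chr1", (0:999) * 5000, (0:999) * 5000 + 1000)
    states <- factor(rep(NAMED_STATES, c(100, 225, 225, 225, 225)),
                     levels = STATE_LEVELS)
    bound <- c(1:50)  # 50 regions, all in the 100-region active group
    fp <- bedRanges("chr1", (bound - 1) * 5000 + 200,
                    (bound - 1) * 5000 + 600)
    enr <- enrichFactors(regions, states, list(tfX = fp))
    top <- enr[1, ]
    expect_equal(top$state, "active")
    expect_equal(top$k, 50L); expect_equal(top$n, 50L)
    expect_lt(top$p_value, 1e-10)
    expect_equal(top$fraction_bound, 0.5)
    # Bonferroni: never smaller than raw, capped at 1, m = factors x states
    expect_true(all(enr$p_adjusted >= enr$p_value - 1e-15))
    expect_true(all(enr$p_adjusted <= 1))
    expect_equal(attr(enr, "m"), 5L)
    expect_equal(enr$p_adjusted,
                 pmin(1, enr$p_value * attr(enr, "m")))
})

test_that("overlap fractions against an external set count covered regions", {
    regions <- bedRanges("chr1", c(0, 2000, 4000, 6000),
                         c(1000, 3000, 5000, 7000))
    states <- factor(rep("active", 4), levels = STATE_LEVELS)
    # identical set
    self <- overlapFractionWithSet(regions, states, regions)
    expect_equal(self$fraction_overlapping[self$state == "active"], 1.0)
    # different chromosome
    other <- overlapFractionWithSet(regions, states,
                                    bedRanges("chr2", 0, 1000))
    expect_equal(other$fraction_overlapping[other$state == "active"], 0.0)
    # 3 regions 30% covered, 1 region 10% covered at the 25% rule
    ext <- bedRanges("chr1", c(0, 2000, 4000, 6000),
                     c(300, 2300, 4300, 6100))
    mixed <- overlapFractionWithSet(regions, states, ext)
    expect_equal(mixed$fraction_overlapping[mixed$state == "active"], 0.75)
    # empty state group reports NA, not zero
    expect_true(is.na(
        self$fraction_overlapping[self$state == "bivalent"]))
})

test_that("a uniformly binding factor is calibrated and a planted 8:1 factor ranks its state first", {
    nf <- 40L
    fs <- data.frame(
        factor_id = c(sprintf("null_%02d", seq_len(nf)), "biv8"),
        preferred_state = c(rep(NA_character_, nf), "bivalent"),
        odds_ratio = c(rep(1, nf), 8),
        n_peaks = c(rep(60L, nf), 80L), stringsAsFactors = FALSE)
    b <- generateDataset(tinyConfig(seed = 23,
        n_enhancers_per_state = c(active = 60L, bivalent = 60L,
                                  h3k4me1_only = 60L, h3k27ac_only = 60L,
                                  h3k27me3_only = 60L),
        factor_specs = fs))
    es <- classifyBundle(b)
    enr <- enrichFactors(SummarizedExperiment::rowRanges(es),
                         stateCalls(es), b$factorPeaks)
    nulls <- enr[grepl("^null_", enr$factor_id), ]
    typeI <- mean(nulls$p_value < 0.05)
    expect_gte(typeI, 0.0); expect_lte(typeI, 0.10)  # 200 null tests
    biv <- enr[enr$factor_id == "biv8", ]
    expect_equal(biv$state[which.min(biv$p_adjusted)], "bivalent")
})
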