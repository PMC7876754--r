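simpleGeneModels <- function() {
    geneModelsFromFrame(data.frame(
        gene_id = c("gA", "gB"), chrom = "chr1", tss = c(0, 10000),
        strand = "+", tx_start = c(0, 10000), tx_end = c(6000, 16000),
        exon_starts = c("0,5000", "10000"), exon_ends = c("1000,6000", "16000"),
        promoter_class = c("bivalent", "active"),
        stringsAsFactors = FALSE))
}

test_that("nearest-gene assignment reports distances and regions-per-gene", {
    gm <- simpleGeneModels()
    # midpoints at 1000 and 9000 split between the two TSSs
    regions <- bedRanges("chr1", c(500, 8500), c(1500, 9500))
    ng <- assignNearestGene(regions, gm)
    expect_equal(ng$assignments$gene_id, c("gA", "gB"))
    expect_equal(ng$assignments$distance, c(1000L, 1000L))
    expect_equal(ng$mean_regions_per_gene, 1.0)
    # five regions on one gene
    solo <- bedRanges("chr1", 100 * (1:5), 100 * (1:5) + 50)
    expect_equal(assignNearestGene(solo, gm)$mean_regions_per_gene, 5.0)
    # off-table chromosome is flagged, not dropped silently
    mixed <- suppressWarnings(c(regions, bedRanges("chrX", 0, 100)))
    ngm <- suppressMessages(assignNearestGene(mixed, gm))
    expect_equal(ngm$n_unassigned, 1L)
    expect_true(is.na(ngm$assignments$gene_id[3]))
})

test_that("distance bins are left-closed with edges at 5 kb and 50 kb", {
    b <- binDistances(c(1000, 60000))
    expect_equal(b$fraction[b$bin == "lt5kb"], 0.5)
    expect_equal(b$fraction[b$bin == "b5to50kb"], 0)
    expect_equal(b$fraction[b$bin == "gt50kb"], 0.5)
    # boundary lands in the upper bin
    expect_equal(binDistances(5000)$fraction[2], 1)
    expect_equal(binDistances(rep(0, 4))$fraction[1], 1)
    # per state, fractions sum to 1
    set.seed(5)
    d <- sample.int(1e5, 200)
    st <- sample(NAMED_STATES, 200, replace = TRUE)
    bb <- binDistances(d, st)
    sums <- tapply(bb$fraction, bb$state, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("location annotation follows the stated midpoint priority", {
    gm <- simpleGeneModels()
    loc <- annotateLocation(
        bedRanges("chr1", c(600, 2900, 100000), c(800, 3100, 100100)), gm)
    # exon mid=700 outside the TSS window; intron mid=3000; intergenic
    expect_equal(as.character(loc), c("exon", "intron", "intergenic"))
    # TSS window beats exon: gB TSS at 10000
    expect_equal(as.character(annotateLocation(
        bedRanges("chr1", 9900, 10100), gm)), "tss_5prime")
    # TTS window beats exon: gA TTS at 5999, midpoint 5500 is exon but
    # 5800-6200 has midpoint 6000 inside the TTS window
    expect_equal(as.character(annotateLocation(
        bedRanges("chr1", 5800, 6200), gm)), "tts_3prime")
    # permuting gene records changes nothing
    gmRev <- geneModelsFromFrame(data.frame(
        gene_id = c("gB", "gA"), chrom = "chr1", tss = c(10000, 0),
        strand = "+", tx_start = c(10000, 0), tx_end = c(16000, 6000),
        exon_starts = c("10000", "0,5000"), exon_ends = c("16000", "1000,6000"),
        stringsAsFactors = FALSE))
    rnd <- bedRanges("chr1", (0:40) * 400, (0:40) * 400 + 300)
    expect_identical(annotateLocation(rnd, gm), annotateLocation(rnd, gmRev))
})

test_that("conservation uses the strict more-than-75% rule", {
    regions <- bedRanges("chr1", c(0, 2000), c(1000, 3000))
    blocks <- bedRanges("chr1", c(0, 2000), c(800, 2700))  # 0.8 and 0.7
    cs <- conservationStatus(regions, blocks,
                             states = factor(c("active", "active")))
    expect_equal(cs$conserved, c(TRUE, FALSE))
    expect_equal(cs$fraction, c(0.8, 0.7))
    expect_equal(cs$per_state$conserved_fraction, 0.5)
    # empty conserved set: nothing conserved
    none <- conservationStatus(regions, GenomicRanges::GRanges())
    expect_false(any(none$conserved))
    # exactly 75% is NOT conserved under the strict rule, but is under >=
    edge <- bedRanges("chr1", 0, 750)
    expect_false(conservationStatus(regions[1], edge)$conserved)
    expect_true(conservationStatus(regions[1], edge,
                                   inclusive = TRUE)$conserved)
    # per-state fractions equal a brute-force recount
    set.seed(77)
    rr <- randomIntervals(300, maxCoord = 9000, maxWidth = 200)
    bl <- randomIntervals(150, maxCoord = 9000, maxWidth = 300)
    st <- factor(sample(NAMED_STATES, 300, replace = TRUE))
    full <- conservationStatus(rr, bl, states = st)
    for (s in levels(st)) {
        brute <- mean(vapply(which(st == s), function(i)
            oracleCoverageFraction(rr[i], bl) > 0.75, TRUE))
        expect_equal(
            full$per_state$conserved_fraction[full$per_state$state == s],
            brute)
    }
})

test_that("gene-group overlap reproduces closed-form hypergeometric corners", {
    universe <- sprintf("g%03d", 1:100)
    ten <- universe[1:10]
    grid <- geneGroupOverlap(list(active = ten), list(active = ten), universe)
    expect_equal(grid$k, 10L)
    expect_equal(grid$p_value, 1 / choose(100, 10), tolerance = 1e-12)
    # disjoint sets are maximally unenriched
    dis <- geneGroupOverlap(list(a = universe[1:10]),
                            list(b = universe[11:20]), universe)
    expect_equal(dis$k, 0L)
    expect_equal(dis$p_value, 1)
    expect_error(geneGroupOverlap(list(a = "zzz"), list(b = ten), universe),
                 "outside the universe")
    expect_error(geneGroupOverlap(list(a = ten), list(b = ten), character()),
                 "empty")
})

test_that("bivalent enhancers planted near bivalent-promoter genes rank first in the overlap grid", {
    b <- generateDataset(tinyConfig(seed = 17,
        n_enhancers_per_state = c(active = 40L, bivalent = 40L,
                                  h3k4me1_only = 30L),
        bivalent_near_bivalent_gene_odds = 12))
    es <- classifyBundle(b)
    regions <- SummarizedExperiment::rowRanges(es)
    ng <- suppressMessages(assignNearestGene(regions, b$geneModels))
    enh <- enhancerGeneSets(ng$assignments, stateCalls(es))
    tss <- tssPoints(b$geneModels)
    gid <- S4Vectors::mcols(tss)$gene_id
    prom <- split(gid, S4Vectors::mcols(tss)$promoter_class)
    grid <- geneGroupOverlap(enh[intersect(names(enh), NAMED_STATES)],
                             prom, gid)
    top <- grid[1, ]
    expect_equal(paste(top$enhancer_state, top$promoter_class),
                 "bivalent bivalent")
})
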