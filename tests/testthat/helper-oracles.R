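# Independent oracles: per-base set arithmetic, exhaustive hypergeometric
# enumeration, and a hand-written classification predicate. Deliberately
# naive; they never share code with the implementation they check.

# per-base representation: character set "chrom:pos" (0-based positions)
oracleBases <- function(gr) {
    df <- bedCoords(gr)
    unlist(lapply(seq_len(nrow(df)), function(i)
        paste(df$chrom[i], seq(df$start[i], df$end[i] - 1L), sep = ":")))
}

oracleOverlapBp <- function(a, b) {
    length(intersect(unique(oracleBases(a)), unique(oracleBases(b))))
}

oracleCoverageFraction <- function(region, blocks) {
    rb <- unique(oracleBases(region))
    if (length(blocks) == 0L) return(0)
    length(intersect(rb, unique(oracleBases(blocks)))) / length(rb)
}

# exhaustive fixpoint check for mergeByFraction output: no remaining pair
# qualifies, and every input interval is contained in some output span
oracleMergeIsFixpoint <- function(input, output, minFrac) {
    n <- length(output)
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            ov <- oracleOverlapBp(output[i], output[j])
            if (ov >= minFrac * min(GenomicRanges::width(output[i]),
                                    GenomicRanges::width(output[j])))
                return(FALSE)
        }
    }
    outB <- unique(oracleBases(output))
    for (i in seq_along(input))
        if (!all(oracleBases(input[i]) %in% outB)) return(FALSE)
    # merged components are unions of overlapping chains: base sets match
    setequal(unique(oracleBases(input)), outB)
}

# P(X >= k) by enumerating every K-subset of an N-item universe with n
# successes (items 1..n) and counting subsets with >= k successes
oracleHyperTail <- function(k, K, n, N) {
    if (K == 0L) return(if (k <= 0) 1 else 0)
    subsets <- utils::combn(N, K)
    mean(colSums(subsets <= n) >= k)
}

# hand-written restatement of the published five-group rule (4 samples,
# present in >= 3, absent in all)
oracleClassify4 <- function(n1, n2, n3) {
    if (n1 >= 3 && n2 >= 3 && n3 == 0) return("active")
    if (n1 >= 3 && n3 >= 3 && n2 == 0) return("bivalent")
    if (n1 >= 3 && n2 == 0 && n3 == 0) return("h3k4me1_only")
    if (n2 >= 3 && n1 == 0 && n3 == 0) return("h3k27ac_only")
    if (n3 >= 3 && n1 == 0 && n2 == 0) return("h3k27me3_only")
    "unclassified"
}

randomIntervals <- function(n, maxCoord = 10000, chroms = c("chr1", "chr2"),
                            maxWidth = 400) {
    s <- sample.int(maxCoord - maxWidth, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    bedRanges(sample(chroms, n, replace = TRUE), s, s + w)
}

# tiny noise-free simulation config used by several suites
tinyConfig <- function(seed = 42, ...) {
    defaults <- list(
        seed = seed, n_chromosomes = 2L, chrom_length = 5e6,
        n_genes = 60L,
        n_enhancers_per_state = c(active = 30L, bivalent = 12L,
                                  h3k4me1_only = 20L, h3k27ac_only = 6L,
                                  h3k27me3_only = 4L),
        detection_prob = 1.0, boundary_jitter_sd = 0,
        background_peak_rate = 0)
    args <- utils::modifyList(defaults, list(...))
    do.call(simulationConfig, args)
}

classifyBundle <- function(bundle, presenceMin = 3L, absenceMax = 0L) {
    ref <- buildReferenceRegions(bundle$peaksets, 0.25)
    ref <- suppressMessages(
        filterPromoterRegions(ref, bundle$geneModels, 500L))
    es <- buildPresenceMatrix(ref, bundle$peaksets, 0.25)
    classifyStates(es, presenceMin, absenceMax)
}
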