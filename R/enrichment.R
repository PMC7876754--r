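## Factor occupancy, per-region factor counts, hypergeometric enrichment
## with Bonferroni correction, and overlap fractions against external sets.

#' Factor occupancy calls per region
#'
#' A region is occupied by a factor when some factor peak shares strictly
#' more than `occupancyFrac` of the *factor peak's* width with the region
#' (default denominator: histone-mark consensus regions are typically much
#' wider than point-source TF peaks, so the fraction is taken of the
#' narrow peak; `denominator = "region"` selects the other reading).
#'
#' @param regions A `GRanges`.
#' @param factorPeaks A `GRanges` of one factor's peaks.
#' @param occupancyFrac Threshold in (0, 1], default 0.5; comparison is
#'   strict (`>`).
#' @param denominator `"factor"` (default) or `"region"`.
#' @return Logical vector, one call per region.
#' @export
occupancy <- function(regions, factorPeaks, occupancyFrac = 0.5,
                      denominator = c("factor", "region")) {
    denominator <- match.arg(denominator)
    stopifnot(occupancyFrac > 0, occupancyFrac <= 1)
    out <- logical(length(regions))
    if (!length(factorPeaks)) return(out)
    hits <- quietOverlaps(regions, factorPeaks)
    if (!length(hits)) return(out)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- overlapBp(regions[q], factorPeaks[s])
    w <- if (denominator == "factor") width(factorPeaks)[s]
         else width(regions)[q]
    out[unique(q[ov > occupancyFrac * w])] <- TRUE
    out
}

#' Number of distinct factors occupying each region
#'
#' @param regions A `GRanges`.
#' @param factorPeaksets Named list of `GRanges`, one per factor.
#' @param occupancyFrac,denominator Passed to [occupancy()].
#' @return Integer vector of factor counts per region.
#' @export
factorCountPerRegion <- function(regions, factorPeaksets,
                                 occupancyFrac = 0.5,
                                 denominator = "factor") {
    stopifnot(length(factorPeaksets) >= 1L)
    occ <- vapply(factorPeaksets, function(fp)
        occupancy(regions, fp, occupancyFrac, denominator),
        logical(length(regions)))
    as.integer(rowSums(matrix(occ, nrow = length(regions))))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, n, K)`: drawing `K` regions from
#' a universe of `N` containing `n` "successes". Computed with
#' `stats::phyper` on the upper tail (stable in log space internally).
#' Vectorised.
#'
#' @param k Observed successes in the draw.
#' @param K Draw size (e.g. regions of one state).
#' @param n Successes in the universe (e.g. all factor-bound regions).
#' @param N Universe size.
#' @return P(X >= k), in (0, 1].
#' @examples
#' hypergeomTail(4, 4, 5, 10)  # 5/210
#' @export
hypergeomTail <- function(k, K, n, N) {
    if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(n > N) || any(K > N) ||
        any(k > pmin(K, n)))
        stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N")
    stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Factor enrichment per enhancer state
#'
#' For every (factor, state) pair, the hypergeometric upper-tail p-value
#' of the overlap between the factor-bound regions and the state's
#' regions, within the universe of all reference regions; Bonferroni
#' multiplicity is the full batch (factors x states tested). Also reports
#' the fraction of each state's regions bound by the factor.
#'
#' @param regions The full promoter-filtered reference `GRanges` (the
#'   universe).
#' @param states Factor of per-region state calls, parallel to `regions`.
#' @param factorPeaksets Named list of `GRanges`, one per factor.
#' @param statesTested States to test (default the five named states that
#'   occur).
#' @param occupancyFrac,denominator Passed to [occupancy()].
#' @return A data.frame sorted by `p_adjusted`: `factor_id`, `state`, `k`,
#'   `K`, `n`, `N`, `fraction_bound`, `p_value`, `p_adjusted`; attribute
#'   `m` carries the Bonferroni multiplicity.
#' @export
enrichFactors <- function(regions, states, factorPeaksets,
                          statesTested = NULL, occupancyFrac = 0.5,
                          denominator = "factor") {
    stopifnot(length(states) == length(regions))
    if (is.null(names(factorPeaksets)))
        stop("factorPeaksets must be a named list")
    states <- factor(states)
    if (is.null(statesTested))
        statesTested <- intersect(NAMED_STATES, unique(as.character(states)))
    N <- length(regions)
    m <- length(factorPeaksets) * length(statesTested)
    res <- do.call(rbind, lapply(names(factorPeaksets), function(f) {
        bound <- occupancy(regions, factorPeaksets[[f]], occupancyFrac,
                           denominator)
        n <- sum(bound)
        do.call(rbind, lapply(statesTested, function(s) {
            idx <- states == s
            K <- sum(idx); k <- sum(bound & idx)
            data.frame(factor_id = f, state = s, k = k, K = K, n = n,
                       N = N,
                       fraction_bound = if (K > 0) k / K else NA_real_,
                       p_value = hypergeomTail(k, K, n, N),
                       stringsAsFactors = FALSE)
        }))
    }))
    res$p_adjusted <- pmin(1, res$p_value * m)
    res <- res[order(res$p_adjusted, res$p_value, res$factor_id), ]
    rownames(res) <- NULL
    attr(res, "m") <- m
    res
}

#' Overlap fraction of each state's regions with an external set
#'
#' Per state: the fraction of regions with at least `minFrac` of their
#' width covered by the external intervals (union coverage), plus the
#' reciprocal direction — the fraction of external intervals with at
#' least `minFrac` of *their* width covered by that state's regions.
#' Empty state groups report `NA`, never 0.
#'
#' @param regions A `GRanges` of classified regions.
#' @param states Factor of per-region states.
#' @param externalSet A `GRanges`.
#' @param minFrac Threshold, default 0.25 (inclusive).
#' @return A data.frame: `state`, `n`, `fraction_overlapping`,
#'   `n_external`, `fraction_external_hit`.
#' @export
overlapFractionWithSet <- function(regions, states, externalSet,
                                   minFrac = 0.25) {
    stopifnot(minFrac > 0, minFrac <= 1, length(states) == length(regions))
    if (!is.factor(states)) states <- factor(states)  # keep given levels
    cf <- coverageFraction(regions, externalSet)
    do.call(rbind, lapply(levels(states), function(s) {
        idx <- states == s
        n <- sum(idx)
        fwd <- if (n > 0) mean(cf[idx] >= minFrac) else NA_real_
        rev <- if (n > 0 && length(externalSet) > 0)
            mean(coverageFraction(externalSet, regions[idx]) >= minFrac)
        else NA_real_
        data.frame(state = s, n = n, fraction_overlapping = fwd,
                   n_external = length(externalSet),
                   fraction_external_hit = rev, stringsAsFactors = FALSE)
    }))
}
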