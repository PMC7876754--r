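## Consensus reference regions, region x sample presence matrix, and the
## five-state chromatin classification.

#' Build the reference putative-enhancer regions
#'
#' Pools all H3K4me1 peak sets (ES samples plus any external-context sets,
#' e.g. a multi-tissue compendium) and merges them with the fractional-
#' overlap consensus ([mergeByFraction()]). The merged list is the row
#' space of the region-by-sample matrix.
#'
#' @param peaksets List of [PeakSet-class]; non-H3K4me1 sets are ignored.
#' @param mergeFrac Merge threshold, default 0.25.
#' @return A `GRanges` of reference regions.
#' @export
buildReferenceRegions <- function(peaksets, mergeFrac = 0.25) {
    if (methods::is(peaksets, "PeakSet")) peaksets <- list(peaksets)
    k4 <- Filter(function(p) mark(p) == "H3K4me1", peaksets)
    if (!length(k4)) stop("no H3K4me1 peak sets supplied")
    pooled <- unlist(methods::as(lapply(k4, peaks), "GRangesList"))
    if (!length(pooled)) stop("pooled H3K4me1 input is empty")
    mergeByFraction(pooled, mergeFrac)
}

#' Remove promoter-overlapping regions
#'
#' Drops every region overlapping (by >= 1 bp) any promoter window
#' (TSS +/- `promoterHalfwidth`), the promoter filter that turns merged
#' H3K4me1 peaks into putative *enhancers*. The number removed is recorded
#' in `metadata()` and messaged.
#'
#' @param regions A `GRanges`.
#' @param geneModels A [GeneModels-class] object.
#' @param promoterHalfwidth Half-width in bases (default 500, i.e. a 1 kb
#'   window around each TSS).
#' @return The surviving `GRanges`; `metadata()$n_removed` holds the count.
#' @export
filterPromoterRegions <- function(regions, geneModels,
                                  promoterHalfwidth = 500L) {
    stopifnot(promoterHalfwidth > 0)
    prom <- promoterWindows(geneModels, promoterHalfwidth)
    hit <- quietOverlapsAny(regions, prom)
    out <- regions[!hit]
    S4Vectors::metadata(out)$n_removed <- sum(hit)
    message(sprintf("promoter filter: removed %d of %d regions",
                    sum(hit), length(regions)))
    out
}

#' Build the region-by-sample presence matrix
#'
#' Entry (r, s) is 1 iff some peak of sample s overlaps at least
#' `presenceFrac` of region r's width (denominator: the reference region;
#' threshold inclusive). Only ES-context samples become matrix columns by
#' default; external-context sets used for reference building are excluded.
#'
#' @param regions Promoter-filtered reference `GRanges`.
#' @param peaksets List of [PeakSet-class].
#' @param presenceFrac Fraction of the region that must be covered by a
#'   single peak, default 0.25.
#' @param contexts Contexts whose samples become columns (default `"ES"`;
#'   `NULL` keeps all).
#' @return An [EnhancerSet-class].
#' @export
buildPresenceMatrix <- function(regions, peaksets, presenceFrac = 0.25,
                                contexts = "ES") {
    if (!is.null(contexts))
        peaksets <- Filter(function(p) context(p) %in% contexts, peaksets)
    if (!length(peaksets)) stop("no peak sets left for matrix columns")
    pres <- vapply(peaksets, function(ps)
        presenceCall(regions, peaks(ps), presenceFrac), integer(length(regions)))
    pres <- matrix(as.integer(pres), nrow = length(regions),
                   dimnames = list(NULL, vapply(peaksets, function(ps)
                       paste(sampleId(ps), mark(ps), sep = "."), "")))
    cd <- S4Vectors::DataFrame(
        sample_id = vapply(peaksets, sampleId, ""),
        mark = vapply(peaksets, mark, ""),
        context = vapply(peaksets, context, ""),
        row.names = colnames(pres))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(presence = pres), rowRanges = regions, colData = cd)
    methods::new("EnhancerSet", se)
}

## 1 iff some single peak covers >= frac of the region width
presenceCall <- function(regions, pk, frac) {
    if (length(pk) == 0L) return(integer(length(regions)))
    hits <- quietOverlaps(regions, pk)
    if (!length(hits)) return(integer(length(regions)))
    ov <- overlapBp(regions[S4Vectors::queryHits(hits)],
                    pk[S4Vectors::subjectHits(hits)])
    ok <- ov >= frac * width(regions)[S4Vectors::queryHits(hits)]
    out <- integer(length(regions))
    out[unique(S4Vectors::queryHits(hits)[ok])] <- 1L
    out
}

## The classification rule, generalised to per-mark presence thresholds so
## the same function serves 4-replicate ES data and single-replicate
## tissue contexts. A presence threshold of Inf marks a mark with no data
## (presence unattainable; absence trivially satisfied).
classifyCounts <- function(nK4me1, nK27ac, nK27me3,
                           pmK4me1, pmK27ac, pmK27me3, absenceMax) {
    p1 <- nK4me1 >= pmK4me1; p2 <- nK27ac >= pmK27ac; p3 <- nK27me3 >= pmK27me3
    a1 <- nK4me1 <= absenceMax; a2 <- nK27ac <= absenceMax
    a3 <- nK27me3 <= absenceMax
    hit <- cbind(active        = p1 & p2 & a3,
                 bivalent      = p1 & p3 & a2,
                 h3k4me1_only  = p1 & a2 & a3,
                 h3k27ac_only  = p2 & a1 & a3,
                 h3k27me3_only = p3 & a1 & a2)
    nhit <- rowSums(hit)
    if (any(nhit > 1L))
        stop("state predicates not mutually exclusive; check thresholds")
    state <- rep("unclassified", length(nK4me1))
    w <- which(nhit == 1L)
    state[w] <- colnames(hit)[max.col(hit[w, , drop = FALSE])]
    factor(state, levels = STATE_LEVELS)
}

#' Classify regions from per-mark presence counts
#'
#' A region is `active` when H3K4me1 and H3K27ac are each present in at
#' least `presenceMin` samples and H3K27me3 in at most `absenceMax`;
#' `bivalent` swaps the roles of H3K27ac and H3K27me3; the three
#' single-mark states require one mark present and both others absent;
#' anything else is `unclassified`. Defaults (`presenceMin` 3 of 4
#' samples, `absenceMax` 0) follow the published high-confidence rule.
#'
#' @param nK4me1,nK27ac,nK27me3 Integer vectors of per-mark presence
#'   counts (parallel).
#' @param totals Named integer vector or list of samples per mark
#'   (`H3K4me1`, `H3K27ac`, `H3K27me3`), default 4 each.
#' @param presenceMin Minimum samples for "present" (default 3).
#' @param absenceMax Maximum samples for "absent" (default 0).
#' @return Factor of states over [STATE_LEVELS].
#' @examples
#' classifyRegion(4, 3, 0)  # active
#' classifyRegion(3, 0, 3)  # bivalent
#' @export
classifyRegion <- function(nK4me1, nK27ac, nK27me3,
                           totals = c(H3K4me1 = 4L, H3K27ac = 4L,
                                      H3K27me3 = 4L),
                           presenceMin = 3L, absenceMax = 0L) {
    totals <- unlist(totals)
    if (absenceMax >= presenceMin)
        stop("absenceMax must be < presenceMin")
    if (any(presenceMin > totals))
        stop("presenceMin exceeds the number of samples for a mark")
    if (any(nK4me1 > totals[["H3K4me1"]]) ||
        any(nK27ac > totals[["H3K27ac"]]) ||
        any(nK27me3 > totals[["H3K27me3"]]))
        stop("presence counts exceed per-mark sample totals")
    classifyCounts(nK4me1, nK27ac, nK27me3,
                   presenceMin, presenceMin, presenceMin, absenceMax)
}

#' Classify every region of an EnhancerSet
#'
#' Collapses the presence matrix to per-mark counts and applies the state
#' rule row-wise; results land in `rowData` (`n_k4me1`, `n_k27ac`,
#' `n_k27me3`, `state`). Invariant to row and column order.
#'
#' @param es An [EnhancerSet-class].
#' @param presenceMin,absenceMax See [classifyRegion()].
#' @return The `EnhancerSet` with state calls; see [stateCalls()],
#'   [stateCounts()].
#' @export
classifyStates <- function(es, presenceMin = 3L, absenceMax = 0L) {
    cd <- SummarizedExperiment::colData(es)
    pres <- SummarizedExperiment::assay(es, "presence")
    cnt <- function(m) {
        idx <- which(cd$mark == m)
        if (length(idx)) as.integer(rowSums(pres[, idx, drop = FALSE]))
        else integer(nrow(es))
    }
    n1 <- cnt("H3K4me1"); n2 <- cnt("H3K27ac"); n3 <- cnt("H3K27me3")
    totals <- vapply(c("H3K4me1", "H3K27ac", "H3K27me3"),
                     function(m) sum(cd$mark == m), 0L)
    st <- classifyRegion(n1, n2, n3, totals = totals,
                         presenceMin = presenceMin, absenceMax = absenceMax)
    rd <- SummarizedExperiment::rowData(es)
    rd$n_k4me1 <- n1; rd$n_k27ac <- n2; rd$n_k27me3 <- n3; rd$state <- st
    SummarizedExperiment::rowData(es) <- rd
    es
}

#' Sample-support curve for one mark
#'
#' Merges the pooled peaks of one mark's samples into consensus regions
#' and counts, for each N, the regions present in at least N samples
#' (presence = a peak covering >= `presenceFrac` of the region). The
#' resulting sequence over N = 1..samples is monotone non-increasing.
#'
#' @param peaksets List of [PeakSet-class], all of one mark.
#' @param mergeFrac Consensus merge threshold, default 0.25.
#' @param presenceFrac Region-presence threshold, default 0.25.
#' @return Named integer vector, element N = regions in >= N samples.
#' @export
presenceCurve <- function(peaksets, mergeFrac = 0.25, presenceFrac = 0.25) {
    stopifnot(length(peaksets) >= 1L)
    mk <- unique(vapply(peaksets, mark, ""))
    if (length(mk) != 1L)
        stop("presenceCurve expects samples of a single mark, got: ",
             paste(mk, collapse = ", "))
    pooled <- unlist(methods::as(lapply(peaksets, peaks), "GRangesList"))
    regions <- mergeByFraction(pooled, mergeFrac)
    nSamp <- rowSums(matrix(vapply(peaksets, function(ps)
        presenceCall(regions, peaks(ps), presenceFrac),
        integer(length(regions))), nrow = length(regions)))
    stats::setNames(vapply(seq_along(peaksets),
                           function(N) sum(nSamp >= N), 0L),
                    paste0("ge", seq_along(peaksets)))
}
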