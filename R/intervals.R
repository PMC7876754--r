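## Core interval algebra. All user-facing coordinates follow the BED
## convention (0-based, half-open); internally intervals live in GRanges
## (1-based, closed), converted at the boundary by bedRanges()/bedCoords().

#' Build a GRanges from BED-style coordinates
#'
#' Convenience constructor taking 0-based half-open coordinates, the
#' convention of every peak file this package consumes.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open coordinates; `end > start` required.
#' @param ... Further vectors stored as metadata columns.
#' @return A `GRanges`.
#' @examples
#' bedRanges("chr1", 0, 100)          # the first 100 bases of chr1
#' @export
bedRanges <- function(chrom, start, end, ...) {
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(start < 0)) stop("start must be >= 0")
    if (any(end <= start)) stop("end must be > start (zero-width intervals are not allowed)")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    dots <- list(...)
    if (length(dots))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(dots)
    gr
}

#' BED-style coordinates of a GRanges
#'
#' @param gr A `GRanges`.
#' @return A `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   plus any metadata columns.
#' @export
bedCoords <- function(gr) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     stringsAsFactors = FALSE)
    mc <- S4Vectors::mcols(gr)
    if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
    df
}

## canonical sort: chromosomes in alphanumeric seqlevel order, then start, end
canonicalSort <- function(gr) {
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    sort(gr, ignore.strand = TRUE)
}

## findOverlaps/overlapsAny on a shared seqlevel set, so disjoint
## chromosome universes compare silently (they simply never overlap)
quietOverlaps <- function(query, subject) {
    lv <- union(GenomeInfoDb::seqlevels(query),
                GenomeInfoDb::seqlevels(subject))
    GenomeInfoDb::seqlevels(query) <- lv
    GenomeInfoDb::seqlevels(subject) <- lv
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
}

quietOverlapsAny <- function(query, subject) {
    lv <- union(GenomeInfoDb::seqlevels(query),
                GenomeInfoDb::seqlevels(subject))
    GenomeInfoDb::seqlevels(query) <- lv
    GenomeInfoDb::seqlevels(subject) <- lv
    IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Overlap in base pairs between paired intervals
#'
#' Vectorised over parallel pairs (usual recycling). Intervals on different
#' chromosomes overlap by 0; half-open abutting intervals overlap by 0.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return Non-negative integer vector of shared bases.
#' @examples
#' overlapBp(bedRanges("chr1", 0, 100), bedRanges("chr1", 50, 150))  # 50
#' @export
overlapBp <- function(a, b) {
    n <- max(length(a), length(b))
    if (length(a) == 1L) a <- rep(a, n)
    if (length(b) == 1L) b <- rep(b, n)
    stopifnot(length(a) == length(b))
    ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
    ov[as.character(GenomeInfoDb::seqnames(a)) !=
       as.character(GenomeInfoDb::seqnames(b))] <- 0L
    pmax(ov, 0L)
}

#' Fractional overlap between paired intervals
#'
#' The overlap in bases divided by the width of a designated interval.
#' Every caller must state the denominator: the paper's rules use different
#' ones (the reference region for matrix presence, the factor peak for
#' occupancy, either/smaller for peak merging).
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @param denominator `"of_a"`, `"of_b"`, or `"of_smaller"` (width of the
#'   narrower interval, i.e. the fraction "of either" is satisfied best).
#' @return Numeric vector in \[0, 1\].
#' @export
overlapFraction <- function(a, b, denominator) {
    if (missing(denominator))
        stop("'denominator' must be specified explicitly: ",
             "\"of_a\", \"of_b\" or \"of_smaller\"")
    denominator <- match.arg(denominator, c("of_a", "of_b", "of_smaller"))
    n <- max(length(a), length(b))
    if (length(a) == 1L) a <- rep(a, n)
    if (length(b) == 1L) b <- rep(b, n)
    w <- switch(denominator,
        of_a = width(a),
        of_b = width(b),
        of_smaller = pmin(width(a), width(b)))
    overlapBp(a, b) / w
}

#' Merge intervals whose fractional overlap meets a threshold
#'
#' The peak-consensus primitive: any pair of intervals sharing at least
#' `minFrac` of the width of either one is replaced by its union span, and
#' this is iterated to a fixpoint, so the result contains no qualifying
#' pair. Pairs overlapping by less than the threshold are left separate
#' (unlike `GenomicRanges::reduce`, which merges on any overlap). The
#' result is independent of input order.
#'
#' @param x A `GRanges`, or a list/`GRangesList` of them (pooled).
#' @param minFrac Fraction in (0, 1]; default 0.25, the consensus threshold
#'   used throughout.
#' @return A canonically sorted `GRanges` fixpoint; metadata columns are
#'   dropped (merged spans have no single provenance).
#' @examples
#' mergeByFraction(bedRanges("chr1", c(0, 60), c(100, 160)), 0.25)
#' @export
mergeByFraction <- function(x, minFrac = 0.25) {
    if (!is.numeric(minFrac) || length(minFrac) != 1L ||
        minFrac <= 0 || minFrac > 1)
        stop("minFrac must be a single number in (0, 1]")
    if (is.list(x) || methods::is(x, "GRangesList"))
        x <- unlist(methods::as(x, "GRangesList"))
    if (length(x) == 0L) return(GenomicRanges::granges(x))
    gr <- GenomicRanges::granges(x)  # drop mcols
    repeat {
        gr <- canonicalSort(gr)
        chr <- as.character(GenomeInfoDb::seqnames(gr))
        s <- start(gr); e <- end(gr)
        n <- length(s)
        out_s <- numeric(n); out_e <- numeric(n); out_c <- character(n)
        k <- 0L
        cur_s <- s[1]; cur_e <- e[1]; cur_c <- chr[1]
        changed <- FALSE
        for (i in seq_len(n)[-1]) {
            ov <- min(cur_e, e[i]) - s[i] + 1
            if (chr[i] == cur_c && ov > 0 &&
                ov >= minFrac * min(cur_e - cur_s + 1, e[i] - s[i] + 1)) {
                cur_e <- max(cur_e, e[i])   # union span; cur_s <= s[i]
                changed <- TRUE
            } else {
                k <- k + 1L
                out_s[k] <- cur_s; out_e[k] <- cur_e; out_c[k] <- cur_c
                cur_s <- s[i]; cur_e <- e[i]; cur_c <- chr[i]
            }
        }
        k <- k + 1L
        out_s[k] <- cur_s; out_e[k] <- cur_e; out_c[k] <- cur_c
        gr <- GenomicRanges::GRanges(out_c[seq_len(k)],
                                     IRanges::IRanges(out_s[seq_len(k)],
                                                      out_e[seq_len(k)]))
        if (!changed) break
    }
    unique(canonicalSort(gr))
}

#' Fraction of a region covered by a set of blocks
#'
#' Bases of each region covered by the union of the blocks, divided by the
#' region width; overlapping blocks are counted once.
#'
#' @param regions A `GRanges` of regions.
#' @param blocks A `GRanges` of covering blocks.
#' @return Numeric vector in \[0, 1\], one value per region.
#' @export
coverageFraction <- function(regions, blocks) {
    if (length(blocks) == 0L) return(rep(0, length(regions)))
    blk <- GenomicRanges::reduce(GenomicRanges::granges(blocks),
                                 ignore.strand = TRUE)
    hits <- quietOverlaps(regions, blk)
    ov <- overlapBp(regions[S4Vectors::queryHits(hits)],
                    blk[S4Vectors::subjectHits(hits)])
    covered <- rep(0, length(regions))
    if (length(hits)) {
        agg <- rowsum(as.numeric(ov), S4Vectors::queryHits(hits))
        covered[as.integer(rownames(agg))] <- agg[, 1]
    }
    covered / width(regions)
}

#' Region midpoints (0-based)
#'
#' `floor((start + end) / 2)` in 0-based half-open coordinates — the anchor
#' used for nearest-TSS distance and genomic-location annotation.
#'
#' @param regions A `GRanges`.
#' @return Integer vector of 0-based midpoint positions.
#' @export
midpoint0 <- function(regions) {
    as.integer(floor((start(regions) - 1 + end(regions)) / 2))
}

#' Distance from region midpoints to the nearest point
#'
#' For each region, the absolute distance from its midpoint to the nearest
#' same-chromosome point (e.g. a TSS). Ties are broken deterministically
#' toward the lower position; among points at the identical position, the
#' first in (position, label) order wins.
#'
#' @param regions A `GRanges`.
#' @param points A `GRanges` of width-1 points (mcol `gene_id` optional) or
#'   a data.frame with `chrom` and 0-based `pos` (optional `gene_id`).
#' @param onMissing What to do for a region with no same-chromosome point:
#'   `"error"` (default) or `"na"` (return `NA`, never a silent zero).
#' @return A `data.frame` with `point_index`, `gene_id` (or `NA`),
#'   `position` (0-based) and `distance` per region.
#' @export
nearestPointDistance <- function(regions, points, onMissing = c("error", "na")) {
    onMissing <- match.arg(onMissing)
    if (is.data.frame(points)) {
        pchr <- as.character(points$chrom)
        ppos <- as.integer(points$pos)
        pid <- if (!is.null(points$gene_id)) as.character(points$gene_id)
               else rep(NA_character_, length(ppos))
    } else {
        stopifnot(all(width(points) == 1L))
        pchr <- as.character(GenomeInfoDb::seqnames(points))
        ppos <- start(points) - 1L
        mcid <- S4Vectors::mcols(points)$gene_id
        pid <- if (!is.null(mcid)) as.character(mcid)
               else rep(NA_character_, length(ppos))
    }
    if (length(ppos) == 0L) stop("no points supplied")
    mid <- midpoint0(regions)
    rchr <- as.character(GenomeInfoDb::seqnames(regions))
    n <- length(regions)
    res <- data.frame(point_index = rep(NA_integer_, n),
                      gene_id = rep(NA_character_, n),
                      position = rep(NA_integer_, n),
                      distance = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
    for (ch in unique(rchr)) {
        ri <- which(rchr == ch)
        piAll <- which(pchr == ch)
        if (!length(piAll)) {
            if (onMissing == "error")
                stop(sprintf("no point on chromosome '%s' for %d region(s)",
                             ch, length(ri)))
            next
        }
        ord <- piAll[order(ppos[piAll], pid[piAll])]
        pp <- ppos[ord]
        lo <- findInterval(mid[ri], pp)           # last pp <= mid (0 if none)
        cand_lo <- pmax(lo, 1L)
        cand_hi <- pmin(lo + 1L, length(pp))
        d_lo <- abs(mid[ri] - pp[cand_lo]); d_lo[lo == 0L] <- NA
        d_hi <- abs(mid[ri] - pp[cand_hi]); d_hi[lo >= length(pp)] <- NA
        # lower position wins ties: prefer cand_lo when d_lo <= d_hi
        use_lo <- !is.na(d_lo) & (is.na(d_hi) | d_lo <= d_hi)
        pick <- ifelse(use_lo, cand_lo, cand_hi)
        # duplicate positions: findInterval returns the last of a run of
        # equal positions; step back to the first for a deterministic label
        first_of_run <- match(pp[pick], pp)
        pick <- first_of_run
        sel <- ord[pick]
        res$point_index[ri] <- sel
        res$gene_id[ri] <- pid[sel]
        res$position[ri] <- ppos[sel]
        res$distance[ri] <- abs(mid[ri] - ppos[sel])
    }
    res
}
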