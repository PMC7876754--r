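## Characterisation of classified regions: nearest-TSS gene assignment,
## distance bins, genomic-location categories, conservation status, and
## gene-level overlap between enhancer groups and promoter groups.

DISTANCE_BIN_LEVELS <- c("lt5kb", "b5to50kb", "gt50kb")
LOCATION_LEVELS <- c("tss_5prime", "tts_3prime", "exon", "intron",
                     "intergenic")

#' Assign each region to its nearest gene
#'
#' Nearest-TSS assignment by region midpoint ([nearestPointDistance()]).
#' Regions on chromosomes absent from the TSS table are flagged
#' unassigned (`NA`) rather than erroring, and excluded from the
#' regions-per-gene mean.
#'
#' @param regions A `GRanges`.
#' @param geneModels A [GeneModels-class] object.
#' @return A list: `assignments` (data.frame with `gene_id`, `distance`),
#'   `mean_regions_per_gene`, `n_unassigned`.
#' @export
assignNearestGene <- function(regions, geneModels) {
    tss <- tssPoints(geneModels)
    if (!length(tss)) stop("TSS table is empty")
    nd <- nearestPointDistance(regions, tss, onMissing = "na")
    ass <- data.frame(gene_id = nd$gene_id, distance = nd$distance,
                      stringsAsFactors = FALSE)
    nUn <- sum(is.na(ass$gene_id))
    if (nUn) message(sprintf("nearest-gene: %d region(s) unassigned", nUn))
    perGene <- table(ass$gene_id[!is.na(ass$gene_id)])
    list(assignments = ass,
         mean_regions_per_gene = if (length(perGene)) mean(perGene) else NA_real_,
         n_unassigned = nUn)
}

#' Bin nearest-TSS distances per state
#'
#' Left-closed bins `[0, e1)`, `[e1, e2)`, `[e2, Inf)` with default edges
#' 5 kb and 50 kb. Fractions are per state and sum to 1 (regions with `NA`
#' distance are excluded).
#'
#' @param distances Numeric vector of distances in bases.
#' @param states Optional factor of states (default: one pooled group).
#' @param edges Two strictly increasing bin edges.
#' @return A data.frame: `state`, `bin`, `fraction`, `n`.
#' @export
binDistances <- function(distances, states = NULL, edges = c(5000, 50000)) {
    stopifnot(length(edges) == 2L, diff(edges) > 0)
    if (is.null(states)) states <- rep("all", length(distances))
    states <- droplevels(factor(states))
    bin <- cut(distances, breaks = c(-Inf, edges, Inf),
               labels = DISTANCE_BIN_LEVELS, right = FALSE)
    keep <- !is.na(distances)
    tab <- table(state = states[keep], bin = bin[keep])
    frac <- prop.table(tab, margin = 1)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out)[3] <- "n"
    out$fraction <- as.data.frame(frac)$Freq
    out[, c("state", "bin", "fraction", "n")]
}

#' Genomic-location category of each region
#'
#' Decided by region midpoint so every region gets exactly one category,
#' with priority `tss_5prime` > `tts_3prime` > `exon` > `intron` >
#' `intergenic`. TSS/TTS windows default to +/- 500 b. Gene models
#' without exon detail simply never yield the `exon` category.
#'
#' @param regions A `GRanges`.
#' @param geneModels A [GeneModels-class] object.
#' @param tssWindow,ttsWindow Window half-widths in bases.
#' @return Factor over `tss_5prime`, `tts_3prime`, `exon`, `intron`,
#'   `intergenic`.
#' @export
annotateLocation <- function(regions, geneModels, tssWindow = 500L,
                             ttsWindow = 500L) {
    mid <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(regions),
        IRanges::IRanges(midpoint0(regions) + 1L, midpoint0(regions) + 1L))
    inAny <- function(gr) {
        if (!length(gr)) return(logical(length(mid)))
        quietOverlapsAny(mid, gr)
    }
    win <- function(pts, hw) {
        p0 <- start(pts) - 1L
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(pts),
            IRanges::IRanges(pmax(0L, p0 - hw) + 1L, p0 + hw))
    }
    loc <- rep("intergenic", length(mid))
    loc[inAny(transcripts(geneModels))] <- "intron"
    loc[inAny(exons(geneModels))] <- "exon"
    loc[inAny(win(ttsPoints(geneModels), as.integer(ttsWindow)))] <- "tts_3prime"
    loc[inAny(win(tssPoints(geneModels), as.integer(tssWindow)))] <- "tss_5prime"
    factor(loc, levels = LOCATION_LEVELS)
}

#' Conservation status of regions
#'
#' A region is conserved when more than `conservationFrac` of its width is
#' covered by the union of conserved blocks (strict `>`, following the
#' "more than 75%" rule; the comparison is configurable via `inclusive`).
#'
#' @param regions A `GRanges`.
#' @param conservedBlocks A `GRanges` of conserved blocks.
#' @param conservationFrac Threshold fraction, default 0.75.
#' @param states Optional factor of states for a per-state summary.
#' @param inclusive Use `>=` instead of `>` (default FALSE).
#' @return A list: `conserved` (logical), `fraction` (numeric coverage
#'   fraction per region), `per_state` (data.frame or NULL).
#' @export
conservationStatus <- function(regions, conservedBlocks,
                               conservationFrac = 0.75, states = NULL,
                               inclusive = FALSE) {
    stopifnot(conservationFrac > 0, conservationFrac <= 1)
    cf <- coverageFraction(regions, conservedBlocks)
    cons <- if (inclusive) cf >= conservationFrac else cf > conservationFrac
    perState <- NULL
    if (!is.null(states)) {
        states <- droplevels(factor(states))
        perState <- data.frame(
            state = levels(states),
            n = as.integer(table(states)),
            conserved_fraction = vapply(levels(states), function(s)
                mean(cons[states == s]), 0),
            stringsAsFactors = FALSE)
    }
    list(conserved = cons, fraction = cf, per_state = perState)
}

#' Gene sets neighbouring each enhancer state
#'
#' @param assignments Output `assignments` of [assignNearestGene()].
#' @param states Factor of per-region states (parallel to assignments).
#' @return Named list of unique gene-id vectors, one per state present.
#' @export
enhancerGeneSets <- function(assignments, states) {
    keep <- !is.na(assignments$gene_id)
    split(assignments$gene_id[keep], droplevels(factor(states[keep]))) |>
        lapply(unique)
}

#' Gene-level overlap between enhancer groups and promoter groups
#'
#' For each (enhancer state, promoter class) pair of gene sets over a
#' common gene universe: the intersection size and its hypergeometric
#' enrichment p-value ([hypergeomTail()]), Bonferroni-adjusted over the
#' whole grid.
#'
#' @param enhancerGenes Named list of gene-id vectors per enhancer state.
#' @param promoterGenes Named list of gene-id vectors per promoter class.
#' @param universe Character vector of all genes; every set must be a
#'   subset.
#' @return A data.frame: `enhancer_state`, `promoter_class`, `k`
#'   (intersection), `K`, `n`, `N`, `p_value`, `p_adjusted`.
#' @export
geneGroupOverlap <- function(enhancerGenes, promoterGenes, universe) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty gene universe")
    chk <- function(sets, what) {
        for (nm in names(sets))
            if (!all(sets[[nm]] %in% universe))
                stop(sprintf("%s set '%s' has genes outside the universe",
                             what, nm))
    }
    chk(enhancerGenes, "enhancer"); chk(promoterGenes, "promoter")
    grid <- expand.grid(enhancer_state = names(enhancerGenes),
                        promoter_class = names(promoterGenes),
                        stringsAsFactors = FALSE)
    N <- length(universe)
    res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        eg <- unique(enhancerGenes[[grid$enhancer_state[i]]])
        pg <- unique(promoterGenes[[grid$promoter_class[i]]])
        k <- length(intersect(eg, pg))
        data.frame(enhancer_state = grid$enhancer_state[i],
                   promoter_class = grid$promoter_class[i],
                   k = k, K = length(eg), n = length(pg), N = N,
                   p_value = hypergeomTail(k, length(eg), length(pg), N),
                   stringsAsFactors = FALSE)
    }))
    res$p_adjusted <- pmin(1, res$p_value * nrow(res))
    res[order(res$p_adjusted, res$p_value), ]
}
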