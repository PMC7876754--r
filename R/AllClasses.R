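## Central S4 classes: PeakSet (one sample's peaks), GeneModels (TSS/gene
## annotation), EnhancerSet (region x sample presence matrix + state calls).

#' @include AllGenerics.R
NULL

#' Recognised histone marks
#'
#' Mark labels used throughout the package. `OTHER` covers factor peak sets
#' and any non-histone input carried through the same container.
#' @export
MARK_LEVELS <- c("H3K4me1", "H3K27ac", "H3K27me3", "OTHER")

#' Chromatin state labels
#'
#' The five named enhancer states plus `unclassified` (a region in the
#' reference set whose presence pattern fits no state) and `latent` (no
#' qualifying mark at all, used when re-classifying in another cellular
#' context).
#' @export
STATE_LEVELS <- c("active", "bivalent", "h3k4me1_only", "h3k27ac_only",
                  "h3k27me3_only", "unclassified")

#' @rdname STATE_LEVELS
#' @export
CONTEXT_STATE_LEVELS <- c(STATE_LEVELS, "latent")

#' @rdname STATE_LEVELS
#' @export
NAMED_STATES <- STATE_LEVELS[1:5]

#' PeakSet: one sample's ChIP-seq peaks
#'
#' Holds the called peaks of a single sample for a single histone mark (or a
#' factor/external set via mark `"OTHER"`), tagged with a sample identifier
#' and a cellular context (e.g. `"ES"`, a tissue name, or `"pool"` for a
#' multi-tissue compendium used only to build the reference row space).
#'
#' @slot peaks A [GenomicRanges::GRanges] of peak intervals.
#' @slot sampleId Non-empty sample identifier.
#' @slot mark One of [MARK_LEVELS].
#' @slot context Cellular context label.
#' @export
setClass("PeakSet",
    representation(peaks = "GRanges", sampleId = "character",
                   mark = "character", context = "character"))

setValidity("PeakSet", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "'sampleId' must be a single non-empty string")
    if (length(object@mark) != 1L || !object@mark %in% MARK_LEVELS)
        msg <- c(msg, sprintf("'mark' must be one of: %s",
                              paste(MARK_LEVELS, collapse = ", ")))
    if (length(object@context) != 1L || !nzchar(object@context))
        msg <- c(msg, "'context' must be a single non-empty string")
    if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks A `GRanges` of peaks.
#' @param sampleId Sample identifier.
#' @param mark Histone mark, one of [MARK_LEVELS].
#' @param context Cellular context label (default `"ES"`).
#' @return A [PeakSet-class] object.
#' @examples
#' PeakSet(bedRanges("chr1", 0, 1000), "ES_s1", "H3K4me1")
#' @export
PeakSet <- function(peaks, sampleId, mark, context = "ES") {
    new("PeakSet", peaks = peaks, sampleId = as.character(sampleId),
        mark = as.character(mark), context = as.character(context))
}

#' @describeIn PeakSet-class peak intervals
#' @export
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @describeIn PeakSet-class sample identifier
#' @export
setMethod("sampleId", "PeakSet", function(x) x@sampleId)

#' @describeIn PeakSet-class histone mark
#' @export
setMethod("mark", "PeakSet", function(x) x@mark)

#' @describeIn PeakSet-class cellular context
#' @export
setMethod("context", "PeakSet", function(x) x@context)

setMethod("show", "PeakSet", function(object) {
    cat("PeakSet:", object@sampleId, sprintf("[%s, %s]", object@mark,
        object@context), "with", length(object@peaks), "peaks\n")
})

#' GeneModels: TSS positions and gene structure
#'
#' A validated gene-model table: one record per gene with its TSS point
#' (strand-aware), transcript span and exon extents, plus an optional
#' promoter chromatin-class label per gene (`active`, `bivalent`,
#' `h3k27me3_only`, `latent`) used for enhancer-vs-promoter gene-group
#' overlap analysis.
#'
#' @slot tss Width-1 `GRanges`, one per gene; mcols: `gene_id`, optional
#'   `promoter_class`.
#' @slot transcripts `GRanges` of transcript spans; mcols: `gene_id`.
#' @slot exons `GRanges` of exon extents; mcols: `gene_id`. May be empty,
#'   in which case location annotation degrades gracefully (no `exon`
#'   category).
#' @export
setClass("GeneModels",
    representation(tss = "GRanges", transcripts = "GRanges",
                   exons = "GRanges"))

setValidity("GeneModels", function(object) {
    msg <- character()
    if (!all(width(object@tss) == 1L))
        msg <- c(msg, "all TSS ranges must have width 1")
    gid <- S4Vectors::mcols(object@tss)$gene_id
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, "tss must carry a unique 'gene_id' mcol")
    if (is.null(S4Vectors::mcols(object@transcripts)$gene_id))
        msg <- c(msg, "transcripts must carry a 'gene_id' mcol")
    if (length(object@exons) &&
        is.null(S4Vectors::mcols(object@exons)$gene_id))
        msg <- c(msg, "exons must carry a 'gene_id' mcol")
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModels-class TSS points (width-1 GRanges)
#' @export
setMethod("tssPoints", "GeneModels", function(x) x@tss)

#' @describeIn GeneModels-class transcript spans
#' @export
setMethod("transcripts", "GeneModels", function(x) x@transcripts)

#' @describeIn GeneModels-class exon extents
#' @export
setMethod("exons", "GeneModels", function(x) x@exons)

#' @describeIn GeneModels-class promoter windows (TSS +/- halfwidth, so a
#'   1 kb window at the default halfwidth of 500 b)
#' @param halfwidth Promoter half-width in bases.
#' @export
setMethod("promoterWindows", "GeneModels", function(x, halfwidth = 500L) {
    stopifnot(halfwidth > 0)
    p0 <- start(x@tss) - 1L  # 0-based TSS point
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(x@tss),
        IRanges::IRanges(pmax(0L, p0 - as.integer(halfwidth)) + 1L,
                         p0 + as.integer(halfwidth)))
    S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(x@tss)$gene_id
    gr
})

#' @describeIn GeneModels-class transcription-termination points (width-1,
#'   strand-aware: the transcript end opposite the TSS)
#' @export
setMethod("ttsPoints", "GeneModels", function(x) {
    tx <- x@transcripts
    minus <- as.character(BiocGenerics::strand(tx)) == "-"
    pos <- ifelse(minus, start(tx), end(tx))  # 1-based point
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx),
                                 IRanges::IRanges(pos, pos),
                                 strand = BiocGenerics::strand(tx))
    S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(tx)$gene_id
    gr
})

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels:", length(object@tss), "genes,",
        length(object@exons), "exons",
        if (!is.null(S4Vectors::mcols(object@tss)$promoter_class))
            "(promoter classes present)" else "", "\n")
})

#' EnhancerSet: reference regions by samples presence matrix
#'
#' Extends `RangedSummarizedExperiment`: rows are the promoter-filtered
#' reference putative-enhancer regions, columns are ChIP-seq samples
#' (`colData`: `sample_id`, `mark`, `context`), and the single `presence`
#' assay is binary (1 = some peak of that sample overlaps at least the
#' configured fraction of the region's width). After [classifyStates()],
#' `rowData` carries the per-mark presence counts and the `state` call.
#'
#' @export
setClass("EnhancerSet", contains = "RangedSummarizedExperiment")

setValidity("EnhancerSet", function(object) {
    msg <- character()
    if (!"presence" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "must have a 'presence' assay")
    else {
        p <- SummarizedExperiment::assay(object, "presence")
        if (!all(p %in% c(0L, 1L)))
            msg <- c(msg, "'presence' entries must be 0/1")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sample_id", "mark") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'sample_id' and 'mark'")
    else if (!all(cd$mark %in% MARK_LEVELS))
        msg <- c(msg, "colData 'mark' values must be recognised marks")
    if (length(msg)) msg else TRUE
})

#' @describeIn EnhancerSet-class per-region state calls (factor over
#'   [STATE_LEVELS]); errors if [classifyStates()] has not been run.
#' @export
setMethod("stateCalls", "EnhancerSet", function(x) {
    st <- SummarizedExperiment::rowData(x)$state
    if (is.null(st))
        stop("no state calls present; run classifyStates() first")
    st
})

#' @describeIn EnhancerSet-class per-state region counts (named integer
#'   vector over [STATE_LEVELS])
#' @export
setMethod("stateCounts", "EnhancerSet", function(x) {
    st <- stateCalls(x)
    tab <- table(factor(st, levels = STATE_LEVELS))
    stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "EnhancerSet", function(object) {
    cat("EnhancerSet:", nrow(object), "reference regions x",
        ncol(object), "samples\n")
    cat("  marks:", paste(sort(unique(
        SummarizedExperiment::colData(object)$mark)), collapse = ", "), "\n")
    if (!is.null(SummarizedExperiment::rowData(object)$state)) {
        sc <- stateCounts(object)
        cat("  states:", paste(sprintf("%s=%d", names(sc), sc),
                               collapse = ", "), "\n")
    } else cat("  states: not yet classified\n")
})
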