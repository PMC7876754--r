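## Readers/writers: BED3+ peak files, TSS/gene-model TSV, YAML sample
## manifest, commented TSV result tables. Parsers account for every line
## (accepted + rejected + skipped), so nothing is dropped silently.

#' Read a BED file of intervals
#'
#' Accepts BED3+ (extra columns beyond the fourth are ignored; a fourth
#' column is kept as `name`). `track`, `browser`, `#` comment lines and
#' blank lines are skipped. Coordinates are validated: non-numeric or
#' inverted (`start >= end`) records raise an error naming the file and
#' line number.
#'
#' @param path Path to a BED file.
#' @param keepName Keep a 4th column as the `name` mcol (default TRUE).
#' @return A `GRanges`; `metadata()` records `n_accepted`, `n_skipped` and
#'   the source path.
#' @export
readBed <- function(path, keepName = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
    keep <- which(!skip)
    if (!length(keep)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr) <- list(path = path, n_accepted = 0L,
                                        n_skipped = sum(skip))
        return(gr)
    }
    fields <- strsplit(lines[keep], "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("%s: line %d: expected >= 3 columns, got %d",
                     path, keep[which(nf < 3L)[1]], min(nf)))
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0)
    if (length(bad))
        stop(sprintf("%s: line %d: malformed coordinates '%s'",
                     path, keep[bad[1]],
                     paste(fields[[bad[1]]][2:3], collapse = ", ")))
    inv <- which(end <= start)
    if (length(inv))
        stop(sprintf("%s: line %d: start (%s) must be < end (%s)",
                     path, keep[inv[1]], start[inv[1]], end[inv[1]]))
    gr <- bedRanges(chrom, start, end)
    if (keepName && any(nf >= 4L)) {
        nm <- rep(NA_character_, length(fields))
        has4 <- nf >= 4L
        nm[has4] <- vapply(fields[has4], `[[`, "", 4L)
        S4Vectors::mcols(gr)$name <- nm
    }
    S4Vectors::metadata(gr) <- list(path = path,
                                    n_accepted = length(gr),
                                    n_skipped = sum(skip))
    gr
}

#' Write intervals to a BED file
#'
#' Writes BED3, or BED4 when a name is available: an explicit `name`
#' argument, a `name` mcol, or a `state` mcol (state labels are written
#' verbatim: `active`, `bivalent`, ...). Rows are written in canonical
#' (chrom, start, end) sort order so output files diff stably. Round-trips
#' losslessly through [readBed()].
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name Optional character vector for the BED name column.
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path, name = NULL) {
    if (is.null(name)) {
        mc <- S4Vectors::mcols(gr)
        if (!is.null(mc$name)) name <- as.character(mc$name)
        else if (!is.null(mc$state)) name <- as.character(mc$state)
    }
    ord <- order(as.character(GenomeInfoDb::seqnames(gr)),
                 start(gr), end(gr))
    df <- bedCoords(gr)[ord, c("chrom", "start", "end"), drop = FALSE]
    if (!is.null(name)) df$name <- name[ord]
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a TSS/gene-model table
#'
#' Tab-delimited with header columns: `gene_id`, `chrom`, `tss`, `strand`,
#' `tx_start`, `tx_end`, `exon_starts`, `exon_ends` (comma-separated lists,
#' may be empty), optional `promoter_class`. All coordinates are 0-based
#' half-open; `tss` is a 0-based point. On the minus strand the TSS is the
#' transcript's right edge; a `tss` equal to `tx_end` is accepted and
#' `tx_end - 1` is used as the point coordinate.
#'
#' @param path Path to the TSV.
#' @return A [GeneModels-class] object.
#' @export
readTssTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand", "tx_start", "tx_end")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("TSS table missing column(s): ", paste(miss, collapse = ", "))
    geneModelsFromFrame(df)
}

#' Build GeneModels from a data.frame
#'
#' Same columns as [readTssTable()]. Validates that every TSS lies within
#' its transcript span and every exon within the span, erroring with the
#' offending `gene_id`.
#'
#' @param df A data.frame of gene records.
#' @return A [GeneModels-class] object.
#' @export
geneModelsFromFrame <- function(df) {
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id: ",
             df$gene_id[anyDuplicated(df$gene_id)])
    if (!all(df$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    tss <- as.integer(df$tss)
    # minus-strand TSS given as the half-open right edge -> point = end - 1
    adj <- df$strand == "-" & tss == as.integer(df$tx_end)
    tss[adj] <- tss[adj] - 1L
    bad <- which(tss < df$tx_start | tss >= df$tx_end)
    if (length(bad))
        stop("TSS outside transcript span for gene(s): ",
             paste(df$gene_id[bad], collapse = ", "))
    tssGr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(tss + 1L, tss + 1L), strand = df$strand)
    S4Vectors::mcols(tssGr)$gene_id <- as.character(df$gene_id)
    if (!is.null(df$promoter_class))
        S4Vectors::mcols(tssGr)$promoter_class <- as.character(df$promoter_class)
    txGr <- bedRanges(df$chrom, df$tx_start, df$tx_end)
    BiocGenerics::strand(txGr) <- df$strand
    S4Vectors::mcols(txGr)$gene_id <- as.character(df$gene_id)
    exGr <- GenomicRanges::GRanges()
    if (!is.null(df$exon_starts)) {
        es <- strsplit(ifelse(is.na(df$exon_starts), "", df$exon_starts), ",")
        ee <- strsplit(ifelse(is.na(df$exon_ends), "", df$exon_ends), ",")
        nEx <- lengths(es)
        if (!all(nEx == lengths(ee)))
            stop("exon_starts/exon_ends length mismatch")
        if (sum(nEx) > 0) {
            gid <- rep(as.character(df$gene_id), nEx)
            s0 <- as.numeric(unlist(es)); e0 <- as.numeric(unlist(ee))
            txs <- rep(df$tx_start, nEx); txe <- rep(df$tx_end, nEx)
            badEx <- which(s0 < txs | e0 > txe | e0 <= s0)
            if (length(badEx))
                stop("exon outside transcript span for gene(s): ",
                     paste(unique(gid[badEx]), collapse = ", "))
            exGr <- bedRanges(rep(as.character(df$chrom), nEx), s0, e0)
            S4Vectors::mcols(exGr)$gene_id <- gid
        }
    }
    new("GeneModels", tss = tssGr, transcripts = txGr, exons = exGr)
}

#' Write a GeneModels object as a TSS table
#'
#' @param gm A [GeneModels-class] object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTssTable <- function(gm, path) {
    tss <- tssPoints(gm); tx <- transcripts(gm); ex <- exons(gm)
    gid <- S4Vectors::mcols(tss)$gene_id
    exIdx <- if (length(ex))
        split(seq_along(ex), factor(S4Vectors::mcols(ex)$gene_id, levels = gid))
    else stats::setNames(rep(list(integer(0)), length(gid)), gid)
    df <- data.frame(
        gene_id = gid,
        chrom = as.character(GenomeInfoDb::seqnames(tss)),
        tss = start(tss) - 1L,
        strand = as.character(BiocGenerics::strand(tss)),
        tx_start = start(tx) - 1L,
        tx_end = end(tx),
        exon_starts = vapply(exIdx, function(i)
            paste(start(ex)[i] - 1L, collapse = ","), ""),
        exon_ends = vapply(exIdx, function(i)
            paste(end(ex)[i], collapse = ","), ""),
        stringsAsFactors = FALSE)
    pc <- S4Vectors::mcols(tss)$promoter_class
    if (!is.null(pc)) df$promoter_class <- pc
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## default analysis thresholds, each traceable to the published procedure
defaultThresholds <- function() {
    list(presence_min = 3L,        # mark present in >= 3 samples
         absence_max = 0L,         # "absence in all 4 samples"
         merge_frac = 0.25,        # "overlap of at least 25%" (peak merge)
         presence_frac = 0.25,     # >= 25% of the reference region
         occupancy_frac = 0.5,     # "> 50%" of the factor peak
         conservation_frac = 0.75, # "> 75%" of the region conserved
         promoter_halfwidth = 500L) # "1 kb region around" the TSS
}

#' Read a sample manifest
#'
#' YAML with a `samples` list (each entry: `path`, `sample_id`, `mark`,
#' `context`; context defaults to `"ES"`) and an optional `thresholds`
#' block overriding the defaults (`presence_min` 3, `absence_max` 0,
#' `merge_frac` 0.25, `presence_frac` 0.25, `occupancy_frac` 0.5,
#' `conservation_frac` 0.75, `promoter_halfwidth` 500). Optional top-level
#' keys `tss_table`, `conserved`, `factors_dir`, `contexts_dir` point at
#' companion inputs, resolved relative to the manifest.
#'
#' @param path Path to the YAML manifest.
#' @return A list with `samples` (data.frame), `thresholds` (list), and
#'   any companion paths, of class `"SampleManifest"`.
#' @export
readManifest <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y$samples) || !length(y$samples))
        stop("manifest has no 'samples' entries")
    samples <- do.call(rbind, lapply(seq_along(y$samples), function(i) {
        e <- y$samples[[i]]
        for (f in c("path", "sample_id", "mark"))
            if (is.null(e[[f]]) || !nzchar(e[[f]]))
                stop(sprintf("manifest sample %d: missing '%s'", i, f))
        if (!e$mark %in% MARK_LEVELS)
            stop(sprintf("manifest sample %d: unknown mark '%s'", i, e$mark))
        data.frame(path = e$path, sample_id = e$sample_id, mark = e$mark,
                   context = if (is.null(e$context)) "ES" else e$context,
                   stringsAsFactors = FALSE)
    }))
    th <- defaultThresholds()
    for (k in names(y$thresholds)) {
        if (!k %in% names(th)) stop("unknown threshold: ", k)
        th[[k]] <- y$thresholds[[k]]
    }
    for (k in c("merge_frac", "presence_frac", "occupancy_frac",
                "conservation_frac"))
        if (th[[k]] <= 0 || th[[k]] > 1)
            stop(k, " must be in (0, 1]")
    if (th$absence_max >= th$presence_min)
        stop("absence_max must be < presence_min")
    es <- samples[samples$context == "ES", , drop = FALSE]
    if (nrow(es)) {
        perMark <- table(es$mark)
        if (any(perMark < th$presence_min))
            stop(sprintf(
                "presence_min (%d) exceeds the number of ES samples for mark(s): %s",
                th$presence_min,
                paste(names(perMark)[perMark < th$presence_min], collapse = ", ")))
    }
    out <- list(samples = samples, thresholds = th,
                tss_table = y$tss_table, conserved = y$conserved,
                factors_dir = y$factors_dir, contexts_dir = y$contexts_dir,
                dir = dirname(path))
    class(out) <- "SampleManifest"
    out
}

#' @export
print.SampleManifest <- function(x, ...) {
    cat("SampleManifest:", nrow(x$samples), "samples\n")
    print(table(x$samples$mark, x$samples$context))
    invisible(x)
}

#' Load all PeakSets listed in a manifest
#'
#' @param manifest A manifest from [readManifest()].
#' @return A list of [PeakSet-class] objects.
#' @export
loadPeakSets <- function(manifest) {
    lapply(seq_len(nrow(manifest$samples)), function(i) {
        s <- manifest$samples[i, ]
        p <- s$path
        if (!file.exists(p)) p <- file.path(manifest$dir, s$path)
        PeakSet(readBed(p), s$sample_id, s$mark, s$context)
    })
}

#' Write a result table as commented TSV
#'
#' A `# key: value` header block (deterministic order) followed by a
#' tab-separated table; read back with [readResultTable()].
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param comments Named character/numeric vector written as header lines.
#' @return Invisibly, the path.
#' @export
writeResultTable <- function(df, path, comments = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(comments))
        writeLines(sprintf("# %s: %s", k, comments[[k]]), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
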