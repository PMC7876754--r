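## File-based pipeline stages over a workspace directory. Stages
## communicate only via files, so each is independently runnable; every
## output table carries a provenance header (package version, thresholds,
## input counts).

resultPath <- function(dir, ...) file.path(dir, "results", ...)

provenance <- function(manifest, extra = character()) {
    c(package = paste0("enhancerStates ",
                       as.character(utils::packageVersion("enhancerStates"))),
      vapply(names(manifest$thresholds), function(k)
          as.character(manifest$thresholds[[k]]), "",
          USE.NAMES = TRUE) |>
          stats::setNames(paste0("threshold_",
                                 names(manifest$thresholds))),
      extra)
}

#' Run the synthetic-data stage
#'
#' Materialises a complete synthetic workspace (peaks, genes, factors,
#' conserved blocks, contexts, manifest, truth files) under `dir`.
#'
#' @param dir Workspace directory (created if needed).
#' @param config A [simulationConfig()]; `seed` overrides its seed.
#' @param seed Optional integer seed override.
#' @return The generated bundle, invisibly.
#' @export
runSimulate <- function(dir, config = simulationConfig(), seed = NULL) {
    if (!is.null(seed)) {
        config$seed <- as.integer(seed)
    }
    bundle <- generateDataset(config, dir = dir)
    message("simulate: wrote workspace to ", dir)
    invisible(bundle)
}

#' Run the classification stage
#'
#' Reads the manifest, builds the merged H3K4me1 reference (all contexts,
#' including any pooled compendium), filters promoters, builds the
#' ES-sample presence matrix, classifies states, and writes per-state BED
#' files, the region-by-sample matrix, and a state-count summary under
#' `results/`.
#'
#' @param dir Workspace directory containing `manifest.yaml`.
#' @return The classified [EnhancerSet-class], invisibly.
#' @export
runClassify <- function(dir) {
    mf <- readManifest(file.path(dir, "manifest.yaml"))
    th <- mf$thresholds
    psets <- loadPeakSets(mf)
    if (is.null(mf$tss_table))
        stop("manifest has no 'tss_table'; classification needs promoter filtering")
    gm <- readTssTable(file.path(mf$dir, mf$tss_table))
    ref <- buildReferenceRegions(psets, th$merge_frac)
    nRef <- length(ref)
    ref <- filterPromoterRegions(ref, gm, th$promoter_halfwidth)
    es <- buildPresenceMatrix(ref, psets, th$presence_frac, contexts = "ES")
    es <- classifyStates(es, th$presence_min, th$absence_max)
    dir.create(resultPath(dir), recursive = TRUE, showWarnings = FALSE)
    st <- stateCalls(es)
    regions <- SummarizedExperiment::rowRanges(es)
    for (s in STATE_LEVELS) {
        sel <- regions[st == s]
        writeBed(sel, resultPath(dir, paste0("regions_", s, ".bed")),
                 name = rep(s, length(sel)))
    }
    mat <- cbind(bedCoords(GenomicRanges::granges(regions)),
                 as.data.frame(SummarizedExperiment::assay(es, "presence")),
                 state = as.character(st))
    prov <- provenance(mf, c(n_merged = nRef,
                             n_promoter_removed =
                                 S4Vectors::metadata(ref)$n_removed,
                             n_reference = length(ref)))
    writeResultTable(mat, resultPath(dir, "matrix.tsv"), prov)
    sc <- stateCounts(es)
    writeResultTable(data.frame(state = names(sc), n = as.integer(sc)),
                     resultPath(dir, "state_counts.tsv"), prov)
    message(sprintf("classify: %d reference regions (%d merged, %d promoter-overlapping removed)",
                    length(ref), nRef, S4Vectors::metadata(ref)$n_removed))
    invisible(es)
}

## reload the classified regions written by runClassify
readStateCalls <- function(dir) {
    df <- readResultTable(resultPath(dir, "matrix.tsv"))
    gr <- bedRanges(df$chrom, df$start, df$end)
    S4Vectors::mcols(gr)$state <- factor(df$state, levels = STATE_LEVELS)
    gr
}

#' Run the annotation stage
#'
#' Nearest-gene assignment, distance bins, genomic-location categories and
#' conservation status for the classified regions; writes a per-region
#' annotation table and per-state summaries, plus the enhancer-vs-promoter
#' gene-group overlap grid when the TSS table carries promoter classes.
#'
#' @param dir Workspace directory with `results/matrix.tsv`.
#' @return The per-region annotation data.frame, invisibly.
#' @export
runAnnotate <- function(dir) {
    mf <- readManifest(file.path(dir, "manifest.yaml"))
    if (!file.exists(resultPath(dir, "matrix.tsv")))
        stop("missing stage output 'results/matrix.tsv'; run runClassify() first")
    regions <- readStateCalls(dir)
    st <- S4Vectors::mcols(regions)$state
    gm <- readTssTable(file.path(mf$dir, mf$tss_table))
    ng <- assignNearestGene(regions, gm)
    loc <- annotateLocation(regions, gm)
    ann <- data.frame(bedCoords(GenomicRanges::granges(regions)),
                      state = as.character(st),
                      nearest_gene = ng$assignments$gene_id,
                      distance_bp = ng$assignments$distance,
                      location = as.character(loc),
                      stringsAsFactors = FALSE)
    cons <- NULL
    if (!is.null(mf$conserved)) {
        blocks <- readBed(file.path(mf$dir, mf$conserved))
        cs <- conservationStatus(regions, blocks,
                                 mf$thresholds$conservation_frac,
                                 states = st)
        ann$conserved <- cs$conserved
        ann$conserved_fraction <- cs$fraction
        cons <- cs$per_state
    }
    dir.create(resultPath(dir), recursive = TRUE, showWarnings = FALSE)
    prov <- provenance(mf, c(mean_regions_per_gene =
                                 sprintf("%.4f", ng$mean_regions_per_gene)))
    writeResultTable(ann, resultPath(dir, "annotation.tsv"), prov)
    bins <- binDistances(ng$assignments$distance, st)
    locTab <- as.data.frame(prop.table(table(state = st, location = loc),
                                       margin = 1), stringsAsFactors = FALSE)
    names(locTab)[3] <- "fraction"
    writeResultTable(bins, resultPath(dir, "distance_bins.tsv"), prov)
    writeResultTable(locTab, resultPath(dir, "location_fractions.tsv"), prov)
    if (!is.null(cons))
        writeResultTable(cons, resultPath(dir, "conservation.tsv"), prov)
    pc <- S4Vectors::mcols(tssPoints(gm))$promoter_class
    if (!is.null(pc)) {
        gid <- S4Vectors::mcols(tssPoints(gm))$gene_id
        promSets <- split(gid, pc)
        enhSets <- enhancerGeneSets(ng$assignments, st)
        grid <- geneGroupOverlap(enhSets, promSets, gid)
        writeResultTable(grid, resultPath(dir, "gene_group_overlap.tsv"),
                         prov)
    }
    message("annotate: wrote annotation for ", length(regions), " regions")
    invisible(ann)
}

#' Run the factor-enrichment stage
#'
#' Occupancy calls and hypergeometric enrichment for every factor BED in
#' the manifest's `factors_dir`; skipped with a warning (exit still
#' clean) when no factor files are present.
#'
#' @param dir Workspace directory with `results/matrix.tsv`.
#' @return The enrichment data.frame (or NULL when skipped), invisibly.
#' @export
runEnrich <- function(dir) {
    mf <- readManifest(file.path(dir, "manifest.yaml"))
    if (!file.exists(resultPath(dir, "matrix.tsv")))
        stop("missing stage output 'results/matrix.tsv'; run runClassify() first")
    fdir <- if (!is.null(mf$factors_dir)) file.path(mf$dir, mf$factors_dir)
            else NULL
    beds <- if (!is.null(fdir) && dir.exists(fdir))
        list.files(fdir, pattern = "\\.bed$", full.names = TRUE) else character()
    if (!length(beds)) {
        warning("enrich: no factor peak files found; stage skipped")
        return(invisible(NULL))
    }
    regions <- readStateCalls(dir)
    st <- S4Vectors::mcols(regions)$state
    fps <- stats::setNames(lapply(beds, readBed),
                           sub("\\.bed$", "", basename(beds)))
    enr <- enrichFactors(regions, st, fps,
                         occupancyFrac = mf$thresholds$occupancy_frac)
    cnt <- factorCountPerRegion(regions, fps,
                                mf$thresholds$occupancy_frac)
    prov <- provenance(mf, c(bonferroni_m = attr(enr, "m")))
    writeResultTable(enr, resultPath(dir, "enrichment.tsv"), prov)
    fb <- stats::reshape(enr[, c("factor_id", "state", "fraction_bound")],
                         idvar = "factor_id", timevar = "state",
                         direction = "wide")
    writeResultTable(fb, resultPath(dir, "fraction_bound.tsv"), prov)
    writeResultTable(data.frame(bedCoords(GenomicRanges::granges(regions)),
                                state = as.character(st),
                                n_factors = cnt),
                     resultPath(dir, "factor_counts.tsv"), prov)
    message("enrich: ", length(fps), " factors x ",
            length(unique(enr$state)), " states")
    invisible(enr)
}

#' Run the cross-context dynamics stage
#'
#' Re-classifies the ES reference regions in each context found in the
#' manifest's `contexts_dir` (files named `<context>_<sample>_<mark>.bed`)
#' and writes the long-format transition-fraction table.
#'
#' @param dir Workspace directory with `results/matrix.tsv`.
#' @return The transitions data.frame (or NULL when skipped), invisibly.
#' @export
runDynamics <- function(dir) {
    mf <- readManifest(file.path(dir, "manifest.yaml"))
    if (!file.exists(resultPath(dir, "matrix.tsv")))
        stop("missing stage output 'results/matrix.tsv'; run runClassify() first")
    cdir <- if (!is.null(mf$contexts_dir)) file.path(mf$dir, mf$contexts_dir)
            else NULL
    beds <- if (!is.null(cdir) && dir.exists(cdir))
        list.files(cdir, pattern = "\\.bed$", full.names = TRUE) else character()
    if (!length(beds)) {
        warning("dynamics: no context peak files found; stage skipped")
        return(invisible(NULL))
    }
    regions <- readStateCalls(dir)
    esSt <- S4Vectors::mcols(regions)$state
    parts <- strsplit(sub("\\.bed$", "", basename(beds)), "_")
    ok <- lengths(parts) >= 3L
    if (!all(ok)) stop("context files must be named <context>_<sample>_<mark>.bed")
    ctxOf <- vapply(parts, function(p) paste(p[-c(length(p) - 1, length(p))][1], collapse = "_"), "")
    markOf <- vapply(parts, function(p) p[length(p)], "")
    sampOf <- vapply(parts, function(p) p[length(p) - 1], "")
    out <- list()
    for (cn in unique(ctxOf)) {
        idx <- which(ctxOf == cn)
        psets <- lapply(idx, function(i)
            PeakSet(readBed(beds[i]), paste(cn, sampOf[i], sep = "_"),
                    markOf[i], cn))
        ctxSt <- classifyInContext(regions, psets,
                                   mf$thresholds$presence_min,
                                   mf$thresholds$absence_max,
                                   mf$thresholds$presence_frac)
        out[[cn]] <- transitionFractions(esSt, ctxSt, contextName = cn)
    }
    trans <- do.call(rbind, out)
    writeResultTable(trans, resultPath(dir, "transitions.tsv"),
                     provenance(mf))
    message("dynamics: ", length(unique(trans$context)), " context(s)")
    invisible(trans)
}

#' Run the full pipeline on a workspace
#'
#' Chains classify, annotate, enrich and dynamics; when the workspace
#' holds a truth file (a simulated bundle), also writes a truth-recovery
#' report.
#'
#' @param dir Workspace directory containing `manifest.yaml`.
#' @return A list of the stage outputs, invisibly.
#' @export
runAll <- function(dir) {
    es <- runClassify(dir)
    ann <- runAnnotate(dir)
    enr <- runEnrich(dir)
    dyn <- runDynamics(dir)
    rec <- NULL
    truthBed <- file.path(dir, "truth", "planted_regions.bed")
    if (file.exists(truthBed)) {
        tr <- readBed(truthBed)
        nm <- strsplit(S4Vectors::mcols(tr)$name, "|", fixed = TRUE)
        S4Vectors::mcols(tr)$planted_id <- vapply(nm, `[[`, "", 1L)
        S4Vectors::mcols(tr)$state <- vapply(nm, `[[`, "", 2L)
        regions <- SummarizedExperiment::rowRanges(es)
        rec <- truthRecoveryReport(list(regions = tr), regions,
                                   stateCalls(es))
        writeResultTable(rec$per_state,
                         resultPath(dir, "truth_recovery.tsv"),
                         c(overall_recall = sprintf("%.6f",
                                                    rec$overall_recall)))
    }
    invisible(list(states = es, annotation = ann, enrichment = enr,
                   transitions = dyn, recovery = rec))
}
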