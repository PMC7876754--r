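## Synthetic data with planted ground truth: a small genome with genes,
## planted enhancer regions carrying true state labels, noisy per-sample
## peak realisations (detection dropout + boundary jitter + background),
## factor peak sets with planted state preferences, conserved blocks, and
## per-context peak sets realising a planted transition table.

MARKS3 <- c("H3K4me1", "H3K27ac", "H3K27me3")

## marks truly carried by each state
marksForState <- function(state) {
    switch(as.character(state),
        active = c("H3K4me1", "H3K27ac"),
        bivalent = c("H3K4me1", "H3K27me3"),
        h3k4me1_only = "H3K4me1",
        h3k27ac_only = "H3K27ac",
        h3k27me3_only = "H3K27me3",
        latent = character(0),
        stop("no mark map for state: ", state))
}

#' Simulation configuration
#'
#' Parameters of the synthetic study. Defaults emulate the design that the
#' analysis assumes: 4 ES replicates per histone mark; planted state
#' proportions echoing the relative abundances observed in ES cells
#' (active and H3K4me1-only dominant, bivalent ~7%, the single-acetyl /
#' single-methyl states rare); SICER-scale peak widths (500-2000 b); 90%
#' per-sample detection of a truly carried mark; ~50 b boundary jitter;
#' sparse unplanted background peaks; a bit over half of regions
#' conserved.
#'
#' @param seed Integer master seed; one derived stream per emission stage.
#' @param n_chromosomes,chrom_length Genome shape (default 4 x 10 Mb).
#' @param n_genes Genes across the genome (default 300).
#' @param n_enhancers_per_state Named integer vector over the five states.
#' @param enhancer_width Min/max planted region width in bases.
#' @param samples_per_mark ES replicates per mark (default 4).
#' @param detection_prob Probability a truly carried mark yields a peak in
#'   a given sample.
#' @param boundary_jitter_sd SD in bases of the rounded Gaussian jitter
#'   applied independently to each peak endpoint (width floor 50 b).
#' @param background_peak_rate Unplanted peaks per Mb per sample.
#' @param factor_specs data.frame: `factor_id`, `preferred_state` (NA =
#'   no preference), `odds_ratio`, `n_peaks`.
#' @param conserved_fraction_target Fraction of planted regions made
#'   conserved (fully covered by a conserved block).
#' @param bivalent_near_bivalent_gene_odds Odds of placing a bivalent
#'   enhancer near a bivalent-promoter gene versus any other gene.
#' @param promoter_class_probs Promoter-class label probabilities.
#' @param context_transition_spec Named list: context name -> named list
#'   mapping source state -> named probability vector over target labels
#'   (states or `latent`); unlisted sources keep their ES state.
#' @param min_enhancer_gap Minimum gap between planted regions (keeps
#'   jittered peaks of neighbours from merging).
#' @param tf_peak_width Width of planted factor peaks.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
        seed = 1L,
        n_chromosomes = 4L,
        chrom_length = 1e7,
        n_genes = 300L,
        n_enhancers_per_state = c(active = 520L, bivalent = 70L,
                                  h3k4me1_only = 390L, h3k27ac_only = 20L,
                                  h3k27me3_only = 10L),
        enhancer_width = c(500L, 2000L),
        samples_per_mark = 4L,
        detection_prob = 0.9,
        boundary_jitter_sd = 50,
        background_peak_rate = 5,
        factor_specs = data.frame(
            factor_id = c("tf_pluri", "tf_polycomb", "tf_null"),
            preferred_state = c("active", "bivalent", NA),
            odds_ratio = c(8, 8, 1),
            n_peaks = c(200L, 100L, 100L),
            stringsAsFactors = FALSE),
        conserved_fraction_target = 0.55,
        bivalent_near_bivalent_gene_odds = 5,
        promoter_class_probs = c(active = 0.4, bivalent = 0.15,
                                 h3k27me3_only = 0.05, latent = 0.4),
        context_transition_spec = list(
            tissue = list(
                active = c(active = 0.6, h3k4me1_only = 0.3, latent = 0.1),
                bivalent = c(bivalent = 0.1, h3k4me1_only = 0.7,
                             h3k27ac_only = 0.2),
                h3k4me1_only = c(h3k4me1_only = 0.7, active = 0.2,
                                 latent = 0.1),
                h3k27ac_only = c(h3k27ac_only = 0.5, latent = 0.5),
                h3k27me3_only = c(h3k27me3_only = 0.4, latent = 0.6))),
        min_enhancer_gap = 1000L,
        tf_peak_width = 200L) {
    cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
        chrom_length = as.numeric(chrom_length), n_genes = as.integer(n_genes),
        n_enhancers_per_state = n_enhancers_per_state,
        enhancer_width = as.integer(enhancer_width),
        samples_per_mark = as.integer(samples_per_mark),
        detection_prob = detection_prob,
        boundary_jitter_sd = boundary_jitter_sd,
        background_peak_rate = background_peak_rate,
        factor_specs = factor_specs,
        conserved_fraction_target = conserved_fraction_target,
        bivalent_near_bivalent_gene_odds = bivalent_near_bivalent_gene_odds,
        promoter_class_probs = promoter_class_probs,
        context_transition_spec = context_transition_spec,
        min_enhancer_gap = as.integer(min_enhancer_gap),
        tf_peak_width = as.integer(tf_peak_width))
    stopifnot(cfg$detection_prob >= 0, cfg$detection_prob <= 1,
              cfg$boundary_jitter_sd >= 0, cfg$background_peak_rate >= 0,
              all(cfg$enhancer_width > 0), length(cfg$enhancer_width) == 2L,
              cfg$samples_per_mark >= 1L,
              all(names(cfg$n_enhancers_per_state) %in% NAMED_STATES),
              cfg$conserved_fraction_target >= 0,
              cfg$conserved_fraction_target <= 1,
              abs(sum(cfg$promoter_class_probs) - 1) < 1e-9)
    for (ctx in cfg$context_transition_spec)
        for (src in names(ctx)) {
            p <- ctx[[src]]
            if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
                stop("context transition probabilities for source '", src,
                     "' must be a probability vector")
            bad <- setdiff(names(p), c(NAMED_STATES, "latent"))
            if (length(bad))
                stop("unknown transition target label(s): ",
                     paste(bad, collapse = ", "))
        }
    # feasibility: planted footprint (with gaps) must fit the genome
    need <- sum(cfg$n_enhancers_per_state) *
        (max(cfg$enhancer_width) + 2 * cfg$min_enhancer_gap)
    if (need > 0.5 * cfg$n_chromosomes * cfg$chrom_length)
        stop("infeasible packing: planted regions would occupy more than ",
             "half the genome")
    class(cfg) <- "SimulationConfig"
    cfg
}

## one named, reproducible sub-stream per emission stage so adding a stage
## never perturbs earlier stages' output
stageSeed <- function(seed, stage) {
    stages <- c("genes", "enhancers", "peaks", "pool", "factors",
                "conserved", "contexts")
    i <- match(stage, stages)
    stopifnot(!is.na(i))
    as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

## jittered-grid gene placement: guarantees generous inter-gene gaps
simGenes <- function(cfg) {
    perChrom <- diff(round(seq(0, cfg$n_genes,
                               length.out = cfg$n_chromosomes + 1)))
    rows <- list()
    for (ci in seq_len(cfg$n_chromosomes)) {
        ng <- perChrom[ci]
        if (ng == 0) next
        space <- cfg$chrom_length / (ng + 1)
        tss <- round(seq_len(ng) * space +
                     stats::runif(ng, -0.25, 0.25) * space)
        strand <- sample(c("+", "-"), ng, replace = TRUE)
        len <- round(stats::runif(ng, 5000, 50000))
        txs <- ifelse(strand == "+", tss, pmax(0, tss - len + 1))
        txe <- ifelse(strand == "+",
                      pmin(cfg$chrom_length, tss + len), tss + 1)
        # exons: alternating segments between sorted breakpoints
        exs <- character(ng); exe <- character(ng)
        for (g in seq_len(ng)) {
            nEx <- sample(2:6, 1)
            bp <- sort(round(stats::runif(2 * (nEx - 1), txs[g] + 1,
                                          txe[g] - 1)))
            s0 <- c(txs[g], bp[seq_along(bp) %% 2 == 0])
            e0 <- c(bp[seq_along(bp) %% 2 == 1], txe[g])
            ok <- e0 > s0
            exs[g] <- paste(s0[ok], collapse = ",")
            exe[g] <- paste(e0[ok], collapse = ",")
        }
        rows[[ci]] <- data.frame(
            gene_id = sprintf("gene_c%d_%03d", ci, seq_len(ng)),
            chrom = sprintf("chr%d", ci), tss = tss, strand = strand,
            tx_start = txs, tx_end = txe, exon_starts = exs,
            exon_ends = exe, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df$promoter_class <- sample(names(cfg$promoter_class_probs), nrow(df),
                                replace = TRUE,
                                prob = cfg$promoter_class_probs)
    df
}

## place planted enhancers: non-overlapping, promoter-window-clear, with a
## minimum gap; bivalent ones near bivalent-promoter genes at given odds
simEnhancers <- function(cfg, genes) {
    occupied <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
        g <- genes[genes$chrom == sprintf("chr%d", ci), ]
        IRanges::IRanges(pmax(0, g$tss - 500) + 1, g$tss + 500)
    })
    placeOne <- function(w, chromIdx = NULL, centre = NULL) {
        for (try in 1:200) {
            ci <- if (is.null(chromIdx))
                sample.int(cfg$n_chromosomes, 1) else chromIdx
            s0 <- if (is.null(centre))
                round(stats::runif(1, cfg$min_enhancer_gap,
                                   cfg$chrom_length - w - cfg$min_enhancer_gap))
            else round(centre - w / 2 +
                       stats::runif(1, -1000, 1000))
            if (s0 < cfg$min_enhancer_gap ||
                s0 + w > cfg$chrom_length - cfg$min_enhancer_gap) next
            cand <- IRanges::IRanges(s0 + 1 - cfg$min_enhancer_gap,
                                     s0 + w + cfg$min_enhancer_gap)
            if (!length(IRanges::findOverlaps(cand, occupied[[ci]]))) {
                occupied[[ci]] <<- c(occupied[[ci]],
                                     IRanges::IRanges(s0 + 1, s0 + w))
                return(c(ci, s0))
            }
            if (!is.null(centre) && try > 100) centre <- NULL  # fall back
        }
        stop("infeasible packing: could not place a planted region after ",
             "200 tries")
    }
    states <- names(cfg$n_enhancers_per_state)
    recs <- list(); id <- 0L
    bivGenes <- genes[genes$promoter_class == "bivalent", ]
    for (st in states) {
        for (j in seq_len(cfg$n_enhancers_per_state[[st]])) {
            id <- id + 1L
            w <- round(stats::runif(1, cfg$enhancer_width[1],
                                    cfg$enhancer_width[2]))
            if (st == "bivalent" && nrow(bivGenes) > 0) {
                odds <- ifelse(genes$promoter_class == "bivalent",
                               cfg$bivalent_near_bivalent_gene_odds, 1)
                g <- genes[sample.int(nrow(genes), 1, prob = odds), ]
                ci <- as.integer(sub("chr", "", g$chrom))
                off <- sample(c(-1, 1), 1) * round(stats::runif(1, 2000, 9000))
                pos <- placeOne(w, ci, g$tss + off)
            } else {
                pos <- placeOne(w)
            }
            recs[[id]] <- data.frame(
                planted_id = sprintf("enh_%05d", id),
                chrom = sprintf("chr%d", pos[1]), start = pos[2],
                end = pos[2] + w, state = st, stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, recs)
    gr <- bedRanges(df$chrom, df$start, df$end,
                    planted_id = df$planted_id, state = df$state)
    canonicalSort(gr)
}

## per-sample peak realisation for one mark: dropout + jitter + background
simMarkSample <- function(cfg, planted, mk, sampleIdx) {
    carries <- vapply(S4Vectors::mcols(planted)$state,
                      function(s) mk %in% marksForState(s), TRUE)
    tru <- planted[carries]
    det <- stats::runif(length(tru)) < cfg$detection_prob
    tru <- tru[det]
    s0 <- start(tru) - 1L; e0 <- end(tru)
    if (cfg$boundary_jitter_sd > 0 && length(tru)) {
        s0 <- s0 + round(stats::rnorm(length(tru), 0, cfg$boundary_jitter_sd))
        e0 <- e0 + round(stats::rnorm(length(tru), 0, cfg$boundary_jitter_sd))
        s0 <- pmax(0, s0)
        e0 <- pmin(cfg$chrom_length, pmax(e0, s0 + 50))  # width floor 50 b
    }
    pk <- if (length(tru))
        bedRanges(as.character(GenomeInfoDb::seqnames(tru)), s0, e0,
                  name = S4Vectors::mcols(tru)$planted_id)
    else GenomicRanges::GRanges()
    # background peaks, uniform, avoiding all planted regions
    bg <- list()
    for (ci in seq_len(cfg$n_chromosomes)) {
        nBg <- stats::rpois(1, cfg$background_peak_rate *
                               cfg$chrom_length / 1e6)
        if (nBg == 0) next
        ch <- sprintf("chr%d", ci)
        pl <- IRanges::ranges(planted[
            as.character(GenomeInfoDb::seqnames(planted)) == ch])
        ss <- numeric(0); ww <- numeric(0)
        while (length(ss) < nBg) {  # batch rejection sampling
            nDraw <- 2L * (nBg - length(ss))
            w <- round(stats::runif(nDraw, cfg$enhancer_width[1],
                                    cfg$enhancer_width[2]))
            s <- round(stats::runif(nDraw, 0, cfg$chrom_length - w))
            ok <- if (length(pl))
                !IRanges::overlapsAny(IRanges::IRanges(s + 1, s + w), pl)
            else rep(TRUE, nDraw)
            ss <- c(ss, s[ok]); ww <- c(ww, w[ok])
        }
        ss <- ss[seq_len(nBg)]; ww <- ww[seq_len(nBg)]
        bg[[ci]] <- bedRanges(rep(ch, nBg), ss, ss + ww,
                              name = rep("background", nBg))
    }
    bg <- bg[!vapply(bg, is.null, TRUE)]
    allPk <- if (length(bg))
        suppressWarnings(c(pk, unlist(methods::as(bg, "GRangesList"))))
    else pk
    PeakSet(canonicalSort(allPk),
            sprintf("ES_s%d", sampleIdx), mk, "ES")
}

simFactors <- function(cfg, planted) {
    out <- list()
    specs <- cfg$factor_specs
    for (i in seq_len(nrow(specs))) {
        pref <- specs$preferred_state[i]
        wts <- if (is.na(pref)) rep(1, length(planted))
               else ifelse(S4Vectors::mcols(planted)$state == pref,
                           specs$odds_ratio[i], 1)
        nPk <- min(specs$n_peaks[i], length(planted))
        sel <- sample.int(length(planted), nPk, prob = wts)
        tgt <- planted[sel]
        w <- pmin(cfg$tf_peak_width, width(tgt))
        c0 <- midpoint0(tgt)
        s0 <- pmax(start(tgt) - 1L, c0 - w %/% 2)
        out[[specs$factor_id[i]]] <-
            canonicalSort(bedRanges(
                as.character(GenomeInfoDb::seqnames(tgt)), s0, s0 + w,
                name = S4Vectors::mcols(tgt)$planted_id))
    }
    out
}

simConserved <- function(cfg, planted) {
    nCons <- round(cfg$conserved_fraction_target * length(planted))
    sel <- sort(sample.int(length(planted), nCons))
    consTruth <- logical(length(planted)); consTruth[sel] <- TRUE
    blk <- planted[sel]
    blocks <- bedRanges(as.character(GenomeInfoDb::seqnames(blk)),
                        pmax(0, start(blk) - 1L - 100L), end(blk) + 100L)
    list(blocks = canonicalSort(blocks), conserved = consTruth)
}

simContexts <- function(cfg, planted) {
    out <- list()
    for (ctxName in names(cfg$context_transition_spec)) {
        spec <- cfg$context_transition_spec[[ctxName]]
        src <- as.character(S4Vectors::mcols(planted)$state)
        tgt <- src
        for (s in names(spec)) {
            idx <- which(src == s)
            if (length(idx))
                tgt[idx] <- sample(names(spec[[s]]), length(idx),
                                   replace = TRUE, prob = spec[[s]])
        }
        psets <- lapply(MARKS3, function(mk) {
            has <- vapply(tgt, function(t) mk %in% marksForState(t), TRUE)
            gr <- planted[has]
            gr <- bedRanges(as.character(GenomeInfoDb::seqnames(gr)),
                            start(gr) - 1L, end(gr),
                            name = S4Vectors::mcols(gr)$planted_id)
            PeakSet(canonicalSort(gr), paste0(ctxName, "_s1"), mk, ctxName)
        })
        out[[ctxName]] <- list(peaksets = psets, target_state = tgt)
    }
    out
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Deterministic for a fixed seed (one derived random stream per emission
#' stage). Optionally materialises the bundle as the exact file formats
#' the pipeline consumes (BED peak files, TSS TSV, YAML manifest,
#' conserved-block BED, factor BEDs, per-context BEDs, truth TSVs).
#'
#' @param config A [simulationConfig()].
#' @param dir Optional directory to write the file bundle into.
#' @return A list: `config`, `geneModels`, `truth` (list with `regions` —
#'   planted `GRanges` with `planted_id` and `state` —, `genes`,
#'   `factor_specs`, `conserved`, `context_targets`), `peaksets` (ES
#'   samples + the multi-tissue H3K4me1 `pool` set), `factorPeaks`,
#'   `conservedBlocks`, `contexts`, and `dir` (or NULL).
#' @export
generateDataset <- function(config = simulationConfig(), dir = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed <- function(stage, expr) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(stageSeed(config$seed, stage))
        expr
    }
    genes <- withSeed("genes", simGenes(config))
    gm <- geneModelsFromFrame(genes)
    planted <- withSeed("enhancers", simEnhancers(config, genes))
    peaksets <- withSeed("peaks", {
        out <- list()
        for (mk in MARKS3)
            for (s in seq_len(config$samples_per_mark))
                out[[paste(mk, s, sep = "_")]] <-
                    simMarkSample(config, planted, mk, s)
        out
    })
    # multi-tissue H3K4me1 compendium: every planted region appears, so the
    # reference row space covers all planted states (as the published row
    # space, built from ENCODE tissues + ES, covers regions without ES
    # H3K4me1)
    pool <- PeakSet(bedRanges(
        as.character(GenomeInfoDb::seqnames(planted)),
        start(planted) - 1L, end(planted),
        name = S4Vectors::mcols(planted)$planted_id),
        "tissue_pool", "H3K4me1", "pool")
    peaksets$pool <- pool
    factorPeaks <- withSeed("factors", simFactors(config, planted))
    cons <- withSeed("conserved", simConserved(config, planted))
    contexts <- withSeed("contexts", simContexts(config, planted))
    truth <- list(
        regions = planted,
        genes = genes,
        factor_specs = config$factor_specs,
        conserved = cons$conserved,
        context_targets = do.call(rbind, lapply(names(contexts), function(cn)
            data.frame(planted_id = S4Vectors::mcols(planted)$planted_id,
                       context = cn,
                       source_state = as.character(
                           S4Vectors::mcols(planted)$state),
                       target_state = contexts[[cn]]$target_state,
                       stringsAsFactors = FALSE))))
    bundle <- list(config = config, geneModels = gm, truth = truth,
                   peaksets = peaksets, factorPeaks = factorPeaks,
                   conservedBlocks = cons$blocks,
                   contexts = lapply(contexts, `[[`, "peaksets"),
                   dir = dir)
    if (!is.null(dir)) writeBundle(bundle, dir)
    bundle
}

## materialise a bundle as the on-disk workspace the pipeline consumes
writeBundle <- function(bundle, dir) {
    for (d in c("", "peaks", "factors", "contexts", "truth"))
        dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
    writeTssTable(bundle$geneModels, file.path(dir, "genes.tsv"))
    entries <- list()
    for (nm in names(bundle$peaksets)) {
        ps <- bundle$peaksets[[nm]]
        rel <- file.path("peaks", sprintf("%s_%s_%s.bed", context(ps),
                                          sampleId(ps), mark(ps)))
        writeBed(peaks(ps), file.path(dir, rel))
        entries[[length(entries) + 1L]] <-
            list(path = rel, sample_id = sampleId(ps), mark = mark(ps),
                 context = context(ps))
    }
    for (f in names(bundle$factorPeaks))
        writeBed(bundle$factorPeaks[[f]],
                 file.path(dir, "factors", paste0(f, ".bed")))
    writeBed(bundle$conservedBlocks, file.path(dir, "conserved.bed"))
    for (cn in names(bundle$contexts))
        for (ps in bundle$contexts[[cn]])
            writeBed(peaks(ps), file.path(dir, "contexts",
                sprintf("%s_%s_%s.bed", cn, sampleId(ps), mark(ps))))
    tr <- bundle$truth$regions
    writeBed(tr, file.path(dir, "truth", "planted_regions.bed"),
             name = paste(S4Vectors::mcols(tr)$planted_id,
                          S4Vectors::mcols(tr)$state, sep = "|"))
    utils::write.table(bundle$truth$context_targets,
                       file.path(dir, "truth", "context_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(samples = entries,
                          tss_table = "genes.tsv",
                          conserved = "conserved.bed",
                          factors_dir = "factors",
                          contexts_dir = "contexts"),
                     file.path(dir, "manifest.yaml"))
    invisible(dir)
}

#' Compare pipeline state calls to the planted truth
#'
#' Matches each planted region to the reference region overlapping it most
#' (planted regions absent from the reference count as recall misses) and
#' computes per-state precision and recall. Reference regions matching no
#' planted region ("background rows") count against precision when called
#' a named state.
#'
#' @param truth The `truth` element of [generateDataset()]'s result.
#' @param regions Reference `GRanges` from the pipeline.
#' @param states Factor of state calls parallel to `regions`.
#' @return A list: `per_state` data.frame (`state`, `n_planted`,
#'   `precision`, `recall`), `overall_recall`, and the planted-to-
#'   reference `matches` vector.
#' @export
truthRecoveryReport <- function(truth, regions, states) {
    planted <- truth$regions
    if (is.null(S4Vectors::mcols(planted)$planted_id))
        stop("truth regions carry no planted ids")
    hits <- quietOverlaps(planted, regions)
    best <- rep(NA_integer_, length(planted))
    if (length(hits)) {
        ov <- overlapBp(planted[S4Vectors::queryHits(hits)],
                        regions[S4Vectors::subjectHits(hits)])
        o <- order(S4Vectors::queryHits(hits), -ov)
        first <- !duplicated(S4Vectors::queryHits(hits)[o])
        best[S4Vectors::queryHits(hits)[o][first]] <-
            S4Vectors::subjectHits(hits)[o][first]
    }
    trueSt <- as.character(S4Vectors::mcols(planted)$state)
    callSt <- rep(NA_character_, length(planted))
    callSt[!is.na(best)] <- as.character(states)[best[!is.na(best)]]
    # reference -> planted (for precision): best planted match per region
    refTruth <- rep(NA_character_, length(regions))
    if (length(hits)) {
        ov <- overlapBp(planted[S4Vectors::queryHits(hits)],
                        regions[S4Vectors::subjectHits(hits)])
        o <- order(S4Vectors::subjectHits(hits), -ov)
        firstR <- !duplicated(S4Vectors::subjectHits(hits)[o])
        refTruth[S4Vectors::subjectHits(hits)[o][firstR]] <-
            trueSt[S4Vectors::queryHits(hits)[o][firstR]]
    }
    hitState <- !is.na(callSt) & callSt == trueSt
    perState <- do.call(rbind, lapply(NAMED_STATES, function(s) {
        nP <- sum(trueSt == s)
        rec <- if (nP) mean(hitState[trueSt == s]) else NA_real_
        called <- which(as.character(states) == s)
        prec <- if (length(called))
            mean(!is.na(refTruth[called]) & refTruth[called] == s)
        else NA_real_
        data.frame(state = s, n_planted = nP, precision = prec,
                   recall = rec, stringsAsFactors = FALSE)
    }))
    # a planted region missing from the reference counts as a miss
    overall <- mean(hitState)
    list(per_state = perState, overall_recall = overall, matches = best)
}
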