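## Cross-context state dynamics: re-classify the ES reference regions in
## another tissue/timepoint and tabulate state-transition fractions.

#' Classify ES reference regions in another cellular context
#'
#' Computes per-mark presence counts for the *same* ES reference regions
#' from one context's peak sets and applies the state rule. Presence
#' thresholds clamp to the available replication (`min(presenceMin,
#' samples of that mark)`, at least 1), since tissue compendia typically
#' provide a single replicate; absence still means zero samples. Regions
#' carrying no mark at all are `latent`; marks with no data in the
#' context cannot be called present.
#'
#' @param regions The ES reference `GRanges`.
#' @param contextPeaksets List of [PeakSet-class] from one context.
#' @param presenceMin,absenceMax State-rule thresholds (defaults 3, 0).
#' @param presenceFrac Region-presence threshold, default 0.25.
#' @return Factor over [CONTEXT_STATE_LEVELS].
#' @export
classifyInContext <- function(regions, contextPeaksets, presenceMin = 3L,
                              absenceMax = 0L, presenceFrac = 0.25) {
    if (!length(contextPeaksets))
        stop("context has no peak sets")
    ctx <- unique(vapply(contextPeaksets, context, ""))
    if (length(ctx) != 1L)
        stop("peak sets span multiple contexts: ",
             paste(ctx, collapse = ", "))
    marks <- c("H3K4me1", "H3K27ac", "H3K27me3")
    counts <- lapply(marks, function(m) {
        sets <- Filter(function(p) mark(p) == m, contextPeaksets)
        if (!length(sets)) return(integer(length(regions)))
        rowSums(matrix(vapply(sets, function(ps)
            presenceCall(regions, peaks(ps), presenceFrac),
            integer(length(regions))), nrow = length(regions)))
    })
    names(counts) <- marks
    totals <- vapply(marks, function(m)
        sum(vapply(contextPeaksets, mark, "") == m), 0L)
    # clamp presence to available replication; Inf = mark absent entirely
    pm <- ifelse(totals >= 1L, pmax(1L, pmin(presenceMin, totals)), Inf)
    st <- classifyCounts(counts$H3K4me1, counts$H3K27ac, counts$H3K27me3,
                         pm[["H3K4me1"]], pm[["H3K27ac"]], pm[["H3K27me3"]],
                         absenceMax)
    out <- as.character(st)
    out[counts$H3K4me1 == 0L & counts$H3K27ac == 0L &
        counts$H3K27me3 == 0L] <- "latent"
    factor(out, levels = CONTEXT_STATE_LEVELS)
}

#' State-transition fractions between ES and another context
#'
#' For each ES source state, the distribution of states the same regions
#' exhibit in the other context. Rows are normalised over all emitted
#' target labels (five states, `unclassified`, `latent`) and sum to 1;
#' an empty source group yields `NA` fractions, never zeros.
#'
#' @param esStates Factor of ES state calls.
#' @param contextStates Factor over [CONTEXT_STATE_LEVELS] from
#'   [classifyInContext()] on the same region universe.
#' @param sourceStates ES states to report (default the five named
#'   states).
#' @param contextName Label recorded in the output.
#' @return Long-format data.frame: `source_state`, `context`,
#'   `target_state`, `fraction`, `n_source`.
#' @export
transitionFractions <- function(esStates, contextStates,
                                sourceStates = NAMED_STATES,
                                contextName = "context") {
    if (length(esStates) != length(contextStates))
        stop("ES and context calls cover different region universes")
    esStates <- factor(esStates, levels = union(STATE_LEVELS,
                                                levels(factor(esStates))))
    contextStates <- factor(contextStates, levels = CONTEXT_STATE_LEVELS)
    do.call(rbind, lapply(sourceStates, function(s) {
        idx <- esStates == s
        n <- sum(idx)
        frac <- if (n > 0)
            as.numeric(table(contextStates[idx])) / n
        else rep(NA_real_, length(CONTEXT_STATE_LEVELS))
        data.frame(source_state = s, context = contextName,
                   target_state = CONTEXT_STATE_LEVELS, fraction = frac,
                   n_source = n, stringsAsFactors = FALSE)
    }))
}
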