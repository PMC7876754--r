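NULL

#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setGeneric("mark", function(x) standardGeneric("mark"))

#' @export
setGeneric("context", function(x) standardGeneric("context"))

#' @export
setGeneric("tssPoints", function(x) standardGeneric("tssPoints"))

#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @export
setGeneric("promoterWindows", function(x, halfwidth = 500L)
    standardGeneric("promoterWindows"))

#' @export
setGeneric("ttsPoints", function(x) standardGeneric("ttsPoints"))

#' @export
setGeneric("stateCalls", function(x) standardGeneric("stateCalls"))

#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))
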