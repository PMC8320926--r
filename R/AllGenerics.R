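#' @include AllGenerics.R
NULL

#' @export
setGeneric("intensityMatrix", function(x, ...) standardGeneric("intensityMatrix"))

#' @export
setGeneric("observedMask", function(x, ...) standardGeneric("observedMask"))

#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @export
setGeneric("metaboliteNames", function(x, ...) standardGeneric("metaboliteNames"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @export
setGeneric("preprocessReport", function(x, ...) standardGeneric("preprocessReport"))

#' @export
setGeneric("selectedMetabolites", function(x, ...) standardGeneric("selectedMetabolites"))

#' @export
setGeneric("knockoffCopies", function(x, ...) standardGeneric("knockoffCopies"))

#' @export
setGeneric("decorrelationVector", function(x, ...) standardGeneric("decorrelationVector"))

#' @export
setGeneric("importanceScores", function(x, ...) standardGeneric("importanceScores"))

#' @export
setGeneric("aggregatedPValues", function(x, ...) standardGeneric("aggregatedPValues"))
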