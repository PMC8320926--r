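#' @include AllClasses.R
NULL

#' Construct a MetaboSet from a samples-by-metabolites intensity matrix
#'
#' @param intensities numeric matrix, samples in rows and metabolites in
#'   columns (the natural orientation of exported feature tables). Missing
#'   measurements are `NA`.
#' @param classes factor or character of per-sample class labels.
#' @param mask optional logical matrix of the same shape, `TRUE` where
#'   observed; defaults to `!is.na(intensities)`.
#' @param metaboliteNames,sampleIds optional unique names; default to the
#'   dimnames of `intensities` or generated `M###` / `S###` labels.
#' @param metadata optional list stored in `metadata()`.
#'
#' @return A [MetaboSet-class]. Internally metabolites are rows and samples
#'   columns, following the `SummarizedExperiment` convention.
#' @examples
#' x <- MetaboSet(matrix(abs(rnorm(12)), 4, 3), classes = rep(c("a", "b"), 2))
#' dim(x)
#' @export
MetaboSet <- function(intensities, classes, mask = NULL,
                      metaboliteNames = NULL, sampleIds = NULL,
                      metadata = list()) {
    intensities <- as.matrix(intensities)
    n <- nrow(intensities); p <- ncol(intensities)
    if (is.null(metaboliteNames))
        metaboliteNames <- colnames(intensities)
    if (is.null(metaboliteNames))
        metaboliteNames <- sprintf("M%03d", seq_len(p))
    if (is.null(sampleIds))
        sampleIds <- rownames(intensities)
    if (is.null(sampleIds))
        sampleIds <- sprintf("S%03d", seq_len(n))
    if (anyDuplicated(metaboliteNames))
        stop("duplicate metabolite names: ",
             paste(unique(metaboliteNames[duplicated(metaboliteNames)]), collapse = ", "))
    if (is.null(mask)) mask <- !is.na(intensities)
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(intensities)))
        stop("mask dimensions must match intensities")
    intensities[!mask] <- NA_real_
    classes <- as.factor(classes)
    if (length(classes) != n)
        stop("length of class labels (", length(classes),
             ") must match the number of samples (", n, ")")
    classes <- droplevels(classes)
    v <- t(intensities); m <- t(mask)
    dimnames(v) <- dimnames(m) <- list(metaboliteNames, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = v, observed = m),
        colData = S4Vectors::DataFrame(class = classes, row.names = sampleIds),
        metadata = metadata)
    methods::new("MetaboSet", se)
}

#' Accessors for MetaboSet and result objects
#'
#' @param x a [MetaboSet-class] (or, where noted, a result object).
#' @param ... unused.
#' @return `intensityMatrix` and `observedMask` return samples-by-metabolites
#'   matrices (the orientation all statistical stages operate on);
#'   `classLabels` the per-sample factor; `metaboliteNames` / `sampleIds`
#'   character vectors; `groundTruth` the simulation ground-truth list (or
#'   `NULL`); `preprocessReport` the accumulated [PreprocessReport-class]
#'   (or `NULL`).
#' @name MetaboSet-accessors
#' @aliases intensityMatrix observedMask classLabels metaboliteNames
#'   sampleIds groundTruth preprocessReport
NULL

#' @rdname MetaboSet-accessors
#' @export
setMethod("intensityMatrix", "MetaboSet", function(x, ...)
    t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname MetaboSet-accessors
#' @export
setMethod("observedMask", "MetaboSet", function(x, ...)
    t(SummarizedExperiment::assay(x, "observed")))

#' @rdname MetaboSet-accessors
#' @export
setMethod("classLabels", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$class)

#' @rdname MetaboSet-accessors
#' @export
setMethod("metaboliteNames", "MetaboSet", function(x, ...) rownames(x))

#' @rdname MetaboSet-accessors
#' @export
setMethod("sampleIds", "MetaboSet", function(x, ...) colnames(x))

#' @rdname MetaboSet-accessors
#' @export
setMethod("groundTruth", "MetaboSet", function(x, ...)
    S4Vectors::metadata(x)$groundTruth)

#' @rdname MetaboSet-accessors
#' @export
setMethod("preprocessReport", "MetaboSet", function(x, ...)
    S4Vectors::metadata(x)$preprocess)

setMethod("show", "MetaboSet", function(object) {
    v <- SummarizedExperiment::assay(object, "observed")
    cat("MetaboSet:", ncol(object), "samples x", nrow(object), "metabolites\n")
    cat("  classes:",
        paste(sprintf("%s (%d)", levels(classLabels(object)),
                      tabulate(classLabels(object))), collapse = ", "), "\n")
    cat(sprintf("  missing entries: %d (%.1f%%)\n",
                sum(!v), 100 * mean(!v)))
    gt <- groundTruth(object)
    if (!is.null(gt))
        cat("  simulated; ", length(gt$signalIndices),
            " truly class-associated metabolites\n", sep = "")
    rep <- preprocessReport(object)
    if (!is.null(rep))
        cat("  preprocessed: t =", rep@t, "%,",
            length(rep@keptMetabolites), "kept,",
            length(rep@droppedMetabolites), "dropped\n")
    invisible(NULL)
})

setMethod("show", "PreprocessReport", function(object) {
    cat("PreprocessReport: t =", object@t, "%\n")
    cat("  kept:", length(object@keptMetabolites),
        " dropped:", length(object@droppedMetabolites), "\n")
    cat("  imputation k:", object@imputationK,
        " standardized:", length(object@center) > 0, "\n")
    invisible(NULL)
})

setMethod("show", "KnockoffModel", function(object) {
    p <- length(object@mu)
    cat("KnockoffModel: p =", p, "\n")
    cat(sprintf("  shrinkage intensity: %.4f\n", object@shrinkage))
    cat(sprintf("  decorrelation s: min %.3f / max %.3f\n",
                min(object@s), max(object@s)))
    invisible(NULL)
})

setMethod("show", "KnockoffDraws", function(object) {
    d <- dim(object@copies[[1]])
    cat("KnockoffDraws: B =", object@B, "copies of a",
        d[1], "x", d[2], "matrix\n")
    invisible(NULL)
})

setMethod("show", "ImportanceScores", function(object) {
    cat("ImportanceScores:", length(object@Z), "columns (",
        length(object@Z) / 2L, "original/knockoff pairs )\n")
    cat(sprintf("  baseline OOB accuracy: %.3f\n", object@oobAccuracy))
    invisible(NULL)
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", length(object@selected), "of",
        length(object@piBar), "metabolites selected at FDR alpha =",
        object@alpha, "\n")
    if (length(object@selected))
        cat("  selected:", paste(utils::head(object@selected, 8), collapse = ", "),
            if (length(object@selected) > 8) "...", "\n")
    if (!is.na(object@bhThreshold))
        cat(sprintf("  BH threshold: %.4g\n", object@bhThreshold))
    pr <- object@provenance
    if (length(pr))
        cat("  provenance: t =", pr$t, " B =", pr$B, " gamma =", pr$gamma,
            " seed =", pr$seed, "\n")
    invisible(NULL)
})

setMethod("show", "SweepResult", function(object) {
    cat("SweepResult over t in {",
        paste(object@counts$t, collapse = ", "), "}\n")
    print(object@counts, row.names = FALSE)
    cat("  union:", length(object@union),
        " intersection:", length(object@intersection), "\n")
    invisible(NULL)
})

#' @rdname MetaboSet-accessors
#' @export
setMethod("selectedMetabolites", "SelectionResult", function(x, ...) x@selected)

#' @rdname MetaboSet-accessors
#' @export
setMethod("aggregatedPValues", "SelectionResult", function(x, ...) x@piBar)

#' @rdname MetaboSet-accessors
#' @export
setMethod("knockoffCopies", "KnockoffDraws", function(x, ...) x@copies)

#' @rdname MetaboSet-accessors
#' @export
setMethod("decorrelationVector", "KnockoffModel", function(x, ...) x@s)

#' @rdname MetaboSet-accessors
#' @export
setMethod("importanceScores", "ImportanceScores", function(x, ...) x@Z)
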