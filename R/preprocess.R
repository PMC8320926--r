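#' @include io.R
NULL

getOrInitReport <- function(x, t = NA_real_) {
    rep <- preprocessReport(x)
    if (is.null(rep))
        rep <- methods::new("PreprocessReport", t = t,
                            keptMetabolites = metaboliteNames(x),
                            droppedMetabolites = character())
    rep
}

setReport <- function(x, rep) {
    S4Vectors::metadata(x)$preprocess <- rep
    x
}

dropMetabolites <- function(x, dropNames) {
    rep <- getOrInitReport(x)
    rep@keptMetabolites <- setdiff(rep@keptMetabolites, dropNames)
    rep@droppedMetabolites <- c(rep@droppedMetabolites, dropNames)
    x <- x[!rownames(x) %in% dropNames, ]
    setReport(x, rep)
}

#' Missingness-threshold prefilter (the t% rule)
#'
#' Keeps a metabolite only if it has an observed, nonzero intensity in at
#' least t% of the samples, i.e. its observed-nonzero count is at least
#' `ceiling(t/100 * n)`. The two extremes are special: at `t = 0` no
#' filtering is applied and the table is returned unchanged; at `t = 100`
#' exactly the complete columns (no missing, no zero-coded-missing entry)
#' survive, which also makes later imputation a no-op.
#'
#' @param x a [MetaboSet-class].
#' @param t threshold in percent, in \[0, 100\].
#' @return The filtered [MetaboSet-class]; the kept and dropped sets are
#'   recorded in its [PreprocessReport-class] (`preprocessReport(x)`).
#' @details The kept set is monotone in t: raising the threshold can only
#'   shrink it. Removing every metabolite is an error, since the pipeline
#'   cannot proceed on an empty table.
#' @examples
#' x <- simulateMetaboSet(nSamples = 40, nMetabolites = 10,
#'                        missingRate = 0.3, seed = 2)
#' preprocessReport(tPercentFilter(x, 60))
#' @export
tPercentFilter <- function(x, t) {
    stopifnot(methods::is(x, "MetaboSet"))
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 100)
        stop("'t' must be a single percentage in [0, 100]")
    rep <- getOrInitReport(x, t)
    rep@t <- t
    if (t == 0) return(setReport(x, rep))
    v <- intensityMatrix(x); m <- observedMask(x)
    n <- nrow(v)
    countNZ <- colSums(m & !is.na(v) & v != 0)
    keep <- countNZ >= ceiling(t / 100 * n)
    if (!any(keep))
        stop("t = ", t, " removes every metabolite; the pipeline cannot proceed")
    x <- setReport(x, rep)
    dropMetabolites(x, metaboliteNames(x)[!keep])
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' Replaces every missing entry (i, j) by the average of metabolite j over
#' the k nearest neighbour samples. Distance between two samples is the
#' Euclidean distance over their co-observed metabolites rescaled by the
#' number of co-observed coordinates (root mean squared difference), so
#' samples with different missingness patterns are comparable. Neighbours
#' that lack an observed value at j are skipped and the next nearest used;
#' if no candidate neighbour observes j, the imputed value falls back to
#' metabolite j's observed mean. Observed entries are never altered.
#'
#' Metabolites with no observed value at all cannot be imputed and are
#' dropped with a warning (this can only happen at `t = 0`, since any
#' positive threshold removes them first).
#'
#' @param x a [MetaboSet-class].
#' @param k number of neighbours, `1 <= k < n` (default 10, the range
#'   recommended for KNN imputation of omics tables).
#' @return A complete [MetaboSet-class] (all-observed mask).
#' @examples
#' x <- simulateMetaboSet(nSamples = 30, nMetabolites = 8,
#'                        missingRate = 0.2, seed = 5)
#' y <- knnImpute(x, k = 5)
#' any(!observedMask(y))
#' @export
knnImpute <- function(x, k = 10L) {
    stopifnot(methods::is(x, "MetaboSet"))
    v <- intensityMatrix(x)
    n <- nrow(v)
    k <- as.integer(k)
    if (k < 1L || k >= n)
        stop("'k' must satisfy 1 <= k < number of samples (", n, ")")
    allMissing <- colSums(!is.na(v)) == 0L
    if (any(allMissing)) {
        warning("dropping ", sum(allMissing),
                " metabolite(s) with no observed value: ",
                paste(colnames(v)[allMissing], collapse = ", "))
        x <- dropMetabolites(x, colnames(v)[allMissing])
        v <- intensityMatrix(x)
    }
    if (!anyNA(v)) {
        rep <- getOrInitReport(x)
        rep@imputationK <- k
        return(setReport(x, rep))
    }
    obs <- !is.na(v)
    colMeansObs <- colMeans(v, na.rm = TRUE)
    out <- v
    needs <- which(rowSums(!obs) > 0L)
    for (i in needs) {
        xi <- v[i, ]; oi <- obs[i, ]
        # rescaled Euclidean distance to every other sample
        diff2 <- sweep(v, 2L, xi)^2
        co <- obs & matrix(oi, nrow(v), ncol(v), byrow = TRUE)
        co[i, ] <- FALSE
        nCo <- rowSums(co)
        d2 <- rowSums(diff2 * co, na.rm = TRUE)
        d <- ifelse(nCo > 0L, sqrt(d2 / nCo), Inf)
        d[i] <- Inf
        ord <- order(d)
        ord <- ord[is.finite(d[ord])]
        for (j in which(!oi)) {
            donors <- ord[obs[ord, j]]
            if (length(donors) == 0L) {
                out[i, j] <- colMeansObs[j]
            } else {
                out[i, j] <- mean(v[donors[seq_len(min(k, length(donors)))], j])
            }
        }
    }
    rep <- getOrInitReport(x)
    rep@imputationK <- k
    y <- MetaboSet(out, classes = classLabels(x),
                   metaboliteNames = metaboliteNames(x),
                   sampleIds = sampleIds(x),
                   metadata = S4Vectors::metadata(x))
    setReport(y, rep)
}

#' Standardize every metabolite to zero mean and unit variance
#'
#' Centres and scales each column to sample mean 0 and sample SD 1
#' (denominator n - 1, matching the covariance estimate used for knockoff
#' generation). Requires a complete table -- run [knnImpute()] first, or
#' filter at t = 100. Constant columns cannot be scaled and are dropped
#' with a warning. The applied means and SDs are recorded in the
#' [PreprocessReport-class] for provenance.
#'
#' @param x a complete [MetaboSet-class].
#' @return The standardized [MetaboSet-class].
#' @export
standardizeIntensities <- function(x) {
    stopifnot(methods::is(x, "MetaboSet"))
    v <- intensityMatrix(x)
    if (anyNA(v))
        stop("table still has missing entries; impute (or filter at t = 100) first")
    ctr <- colMeans(v)
    sds <- apply(v, 2L, stats::sd)
    const <- sds == 0 | !is.finite(sds)
    if (any(const)) {
        warning("dropping ", sum(const), " constant metabolite(s): ",
                paste(colnames(v)[const], collapse = ", "))
        x <- dropMetabolites(x, colnames(v)[const])
        v <- v[, !const, drop = FALSE]
        ctr <- ctr[!const]; sds <- sds[!const]
    }
    z <- sweep(sweep(v, 2L, ctr), 2L, sds, "/")
    rep <- getOrInitReport(x)
    rep@center <- ctr
    rep@scale <- sds
    y <- MetaboSet(z, classes = classLabels(x),
                   metaboliteNames = colnames(v), sampleIds = sampleIds(x),
                   metadata = S4Vectors::metadata(x))
    setReport(y, rep)
}
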