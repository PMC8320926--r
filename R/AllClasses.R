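#' @include AllGenerics.R
NULL

#' MetaboSet: an intensity table with class labels and a missingness mask
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package. It stores an untargeted-metabolomics
#' feature table as two assays with metabolites as rows and samples as
#' columns:
#' \describe{
#'   \item{`intensity`}{numeric peak intensities / abundances; entries that
#'     are missing carry `NA` and never enter any computation.}
#'   \item{`observed`}{logical mask, `TRUE` where the intensity was actually
#'     measured.}
#' }
#' The per-sample class label (e.g. CD / UC / non-IBD) lives in
#' `colData(x)$class` as a factor in which every level is represented at
#' least once. Simulated objects additionally carry their generating ground
#' truth in `metadata(x)$groundTruth` (see [simulateMetaboSet()]), and
#' preprocessed objects carry a [PreprocessReport-class] in
#' `metadata(x)$preprocess`.
#'
#' Most users construct a `MetaboSet` with the [MetaboSet()] constructor,
#' [readFeatureTable()] or [simulateMetaboSet()].
#'
#' @seealso [intensityMatrix()], [observedMask()], [classLabels()],
#'   [runKnockoffPipeline()]
#' @aliases MetaboSet-class
#' @exportClass MetaboSet
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("intensity", "observed") %in% an))
        msg <- c(msg, "assays must include 'intensity' and 'observed'")
    else {
        v <- SummarizedExperiment::assay(object, "intensity")
        m <- SummarizedExperiment::assay(object, "observed")
        if (!is.logical(m))
            msg <- c(msg, "'observed' assay must be logical")
        else if (anyNA(m))
            msg <- c(msg, "'observed' mask must not contain NA")
        else if (any(!m & !is.na(v)))
            msg <- c(msg, "unobserved entries must carry the NA sentinel")
        else if (any(m & is.na(v)))
            msg <- c(msg, "observed entries must not be NA")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "metabolite names (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    cls <- SummarizedExperiment::colData(object)$class
    if (is.null(cls))
        msg <- c(msg, "colData must contain a 'class' column")
    else {
        if (!is.factor(cls))
            msg <- c(msg, "'class' must be a factor")
        else if (anyNA(cls) || !all(levels(cls) %in% as.character(cls)))
            msg <- c(msg, "every class level must occur at least once and labels must be complete")
    }
    if (length(msg)) msg else TRUE
})

#' Preprocessing provenance report
#'
#' Records what the t% missingness filter, the KNN imputation and the
#' standardization did to a [MetaboSet-class]: which metabolites survived,
#' which were dropped at which stage, the neighbour count used for
#' imputation (`NA` when imputation was not needed, e.g. at t = 100), and
#' the per-metabolite centring/scaling constants applied.
#'
#' @slot t numeric; the missingness threshold in percent (0--100).
#' @slot keptMetabolites character; metabolites surviving all stages so far.
#' @slot droppedMetabolites character; metabolites removed, in drop order.
#' @slot imputationK integer; neighbours used by [knnImpute()], or `NA`.
#' @slot center,scale named numeric; constants applied by
#'   [standardizeIntensities()] (empty until that stage runs).
#' @aliases PreprocessReport-class
#' @exportClass PreprocessReport
setClass("PreprocessReport",
    representation(t = "numeric", keptMetabolites = "character",
                   droppedMetabolites = "character", imputationK = "integer",
                   center = "numeric", scale = "numeric"),
    prototype(t = NA_real_, imputationK = NA_integer_))

setValidity("PreprocessReport", function(object) {
    if (length(intersect(object@keptMetabolites, object@droppedMetabolites)))
        "kept and dropped metabolite sets must be disjoint" else TRUE
})

#' Second-order Gaussian knockoff sampling model
#'
#' The fitted Gaussian model of a standardized feature matrix X from which
#' model-X knockoff copies are drawn. Knockoffs are sampled from the
#' conditional normal \eqn{\tilde X | X \sim N(m(X), V)} with
#' \eqn{m(X) = X - (X - 1\mu') \Sigma^{-1} diag(s)} and
#' \eqn{V = 2\,diag(s) - diag(s)\,\Sigma^{-1} diag(s)}, where s is the
#' equi-correlated decorrelation vector. The conditional pieces are
#' precomputed at fit time.
#'
#' @slot mu length-p column mean vector.
#' @slot sigma p x p covariance (shrinkage-regularized, positive definite).
#' @slot s length-p nonnegative decorrelation vector;
#'   \eqn{cov(X_j, \tilde X_j) = \Sigma_{jj} - s_j}.
#' @slot condCoef the p x p matrix \eqn{\Sigma^{-1} diag(s)}.
#' @slot condCov the conditional covariance V, floored to be PSD.
#' @slot sqrtCondCov symmetric matrix square root of V used for sampling.
#' @slot shrinkage the shrinkage intensity applied to the empirical
#'   covariance (0 = none).
#' @aliases KnockoffModel-class
#' @exportClass KnockoffModel
setClass("KnockoffModel",
    representation(mu = "numeric", sigma = "matrix", s = "numeric",
                   condCoef = "matrix", condCov = "matrix",
                   sqrtCondCov = "matrix", shrinkage = "numeric"))

setValidity("KnockoffModel", function(object) {
    p <- length(object@mu)
    msg <- character()
    if (length(object@s) != p || !all(dim(object@sigma) == p))
        msg <- c(msg, "mu, s and sigma dimensions disagree")
    if (any(object@s < 0))
        msg <- c(msg, "decorrelation vector s must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' A set of B independent knockoff draws
#'
#' Holds the B knockoff copies \eqn{\tilde X^{(b)}} of one feature matrix,
#' together with the per-copy RNG seeds that make each copy individually
#' reproducible. Copies are mutually independent given X.
#'
#' @slot copies list of B numeric matrices, each the size of X.
#' @slot seeds integer vector of per-copy seeds (seed xor b).
#' @slot B integer, number of copies.
#' @aliases KnockoffDraws-class
#' @exportClass KnockoffDraws
setClass("KnockoffDraws",
    representation(copies = "list", seeds = "integer", B = "integer"))

setValidity("KnockoffDraws", function(object) {
    msg <- character()
    if (object@B < 1L) msg <- c(msg, "B must be >= 1")
    if (length(object@copies) != object@B || length(object@seeds) != object@B)
        msg <- c(msg, "number of copies/seeds must equal B")
    d <- unique(lapply(object@copies, dim))
    if (length(d) > 1L) msg <- c(msg, "all copies must share dimensions")
    if (length(msg)) msg else TRUE
})

#' Random-forest OOB permutation importance on an augmented matrix
#'
#' Per-column importance scores Z for the 2p columns of a knockoff-augmented
#' matrix: the absolute mean decrease of out-of-bag accuracy under random
#' permutation of the column, averaged over trees. `columnMap` records which
#' augmented column carries original metabolite j and which its knockoff, so
#' scores can be un-scrambled after the optional pair-position swap.
#'
#' @slot Z named numeric, length 2p, nonnegative.
#' @slot columnMap data.frame with columns `column`, `feature`, `role`
#'   (role is "original" or "knockoff"); a perfect pairing over features.
#' @slot oobAccuracy baseline out-of-bag accuracy of the forest.
#' @aliases ImportanceScores-class
#' @exportClass ImportanceScores
setClass("ImportanceScores",
    representation(Z = "numeric", columnMap = "data.frame",
                   oobAccuracy = "numeric"))

setValidity("ImportanceScores", function(object) {
    msg <- character()
    if (any(object@Z < 0)) msg <- c(msg, "Z must be nonnegative (absolute scores)")
    cm <- object@columnMap
    need <- c("column", "feature", "role")
    if (!all(need %in% names(cm)))
        msg <- c(msg, "columnMap must have columns 'column', 'feature', 'role'")
    else {
        p2 <- nrow(cm)
        ok <- p2 == length(object@Z) &&
            all(sort(cm$column) == seq_len(p2)) &&
            all(table(cm$feature, cm$role) == 1L)
        if (!ok) msg <- c(msg, "columnMap must pair every feature's original with exactly one knockoff")
    }
    if (length(msg)) msg else TRUE
})

#' Result of aggregated-knockoff selection
#'
#' The end product of the pipeline: per-draw knockoff-adjusted scores W,
#' per-draw intermediate p-values, their gamma-quantile aggregate, and the
#' Benjamini-Hochberg selection at FDR level alpha. `provenance` keeps the
#' settings (t, B, gamma, seed, ...) needed to reproduce the run.
#'
#' @slot selected character; names of the selected metabolites.
#' @slot alpha nominal FDR level of the BH step-up.
#' @slot bhThreshold largest aggregated p-value passing the step-up rule
#'   (`NA` when nothing is selected).
#' @slot piBar named numeric; aggregated p-values, in (0, 1].
#' @slot piB B x p matrix of per-draw intermediate p-values.
#' @slot W B x p matrix of per-draw knockoff-adjusted scores.
#' @slot gamma quantile level used for aggregation.
#' @slot provenance list of run settings.
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(selected = "character", alpha = "numeric",
                   bhThreshold = "numeric", piBar = "numeric",
                   piB = "matrix", W = "matrix", gamma = "numeric",
                   provenance = "list"),
    prototype(bhThreshold = NA_real_, gamma = NA_real_,
              piB = matrix(numeric(), 0, 0), W = matrix(numeric(), 0, 0)))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (any(object@piBar <= 0 | object@piBar > 1))
        msg <- c(msg, "aggregated p-values must lie in (0, 1]")
    if (!all(object@selected %in% names(object@piBar)))
        msg <- c(msg, "selected metabolites must be among the scored ones")
    if (length(msg)) msg else TRUE
})

#' Result of a t% threshold sweep
#'
#' One [SelectionResult-class] per missingness threshold t, plus the set
#' algebra across thresholds: the union and intersection of selections and
#' a matrix of pairwise overlap counts (the numbers behind Venn-style
#' summaries of threshold sensitivity).
#'
#' @slot results named list of SelectionResult, one per t.
#' @slot union character; metabolites selected at any t.
#' @slot intersection character; metabolites selected at every t.
#' @slot overlap integer matrix of pairwise selection overlap counts.
#' @slot counts data.frame with columns `t` and `nSelected`.
#' @aliases SweepResult-class
#' @exportClass SweepResult
setClass("SweepResult",
    representation(results = "list", union = "character",
                   intersection = "character", overlap = "matrix",
                   counts = "data.frame"))

setValidity("SweepResult", function(object) {
    sel <- lapply(object@results, selectedMetabolites)
    ok <- all(vapply(sel, function(s)
        all(object@intersection %in% s) && all(s %in% object@union),
        logical(1)))
    if (!ok) "intersection must be contained in every per-t selection, and each in the union"
    else TRUE
})
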