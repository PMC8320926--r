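#' @include aggregate.R
NULL

#' Run the full aggregated-knockoff selection pipeline
#'
#' Executes the whole workflow on one feature table at one missingness
#' threshold: t% filter, KNN imputation (skipped at t = 100, where only
#' complete columns survive, and when the table has no missing entries),
#' standardization, Gaussian knockoff model fit, B independent knockoff
#' draws, one random-forest OOB importance run per draw, knockoff-adjusted
#' scores, intermediate p-values, gamma-quantile aggregation and
#' Benjamini-Hochberg selection at level alpha. The defaults (B = 15,
#' gamma = 0.5, alpha = 0.05, k = 10 neighbours, 1000 trees,
#' mtry = sqrt(2p)) are the reference settings of the method.
#'
#' The run is fully reproducible from `seed`: per-draw knockoff noise,
#' per-draw pair-swap patterns and per-draw forest seeds are all derived
#' from it deterministically.
#'
#' @param x a [MetaboSet-class].
#' @param t missingness threshold in percent (see [tPercentFilter()]).
#' @param B number of knockoff draws.
#' @param gamma quantile level of the p-value aggregation.
#' @param alpha FDR control level of the BH step-up.
#' @param knnK neighbours for [knnImpute()].
#' @param nTrees,mtry forest size and candidate features per split
#'   (`NULL` mtry = `round(sqrt(2p))`).
#' @param classWeighting forest class weighting, `"none"` or `"balanced"`.
#' @param swap randomly swap original/knockoff column positions per pair
#'   before fitting each forest (recorded; `FALSE` restores fixed-order
#'   concatenation).
#' @param shrinkage covariance shrinkage passed to [fitKnockoffModel()].
#' @param seed master seed.
#' @param quiet suppress per-stage progress messages.
#' @return A [SelectionResult-class] carrying the per-draw W and
#'   intermediate p-value matrices and full provenance.
#' @examples
#' \donttest{
#' x <- simulateMetaboSet(nSamples = 120, nMetabolites = 50, nSignal = 25,
#'                        effectSize = 1.5, nClasses = 2, missingRate = 0,
#'                        seed = 11)
#' res <- runKnockoffPipeline(x, t = 0, B = 5, nTrees = 100, seed = 11)
#' res
#' }
#' @export
runKnockoffPipeline <- function(x, t = 0, B = 15L, gamma = 0.5, alpha = 0.05,
                                knnK = 10L, nTrees = 1000L, mtry = NULL,
                                classWeighting = "none", swap = TRUE,
                                shrinkage = NULL, seed = 1L, quiet = TRUE) {
    stopifnot(methods::is(x, "MetaboSet"))
    say <- function(...) if (!quiet) message(...)
    say("input: ", ncol(x), " samples x ", nrow(x), " metabolites")

    xf <- withStage("t_percent_filter", tPercentFilter(x, t))
    say("t = ", t, " filter: ", nrow(xf), " metabolites kept")

    if (anyNA(SummarizedExperiment::assay(xf, "intensity"))) {
        xf <- withStage("knn_impute", knnImpute(xf, k = knnK))
        say("imputed with k = ", knnK)
    } else {
        say("no missing entries; imputation skipped")
        rep <- getOrInitReport(xf)
        xf <- setReport(xf, rep)
    }

    xs <- withStage("standardize", standardizeIntensities(xf))
    say("standardized: ", nrow(xs), " metabolites")

    X <- intensityMatrix(xs)
    y <- classLabels(xs)
    model <- withStage("fit_knockoff_model", fitKnockoffModel(X, shrinkage = shrinkage))
    draws <- withStage("sample_knockoffs",
                       sampleKnockoffs(model, X, B = B, seed = seed))

    p <- ncol(X)
    Wmat <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
    piMat <- Wmat
    for (b in seq_len(B)) {
        aug <- withStage("augment",
            augmentWithKnockoffs(X, knockoffCopies(draws)[[b]], swap = swap,
                                 seed = mixSeed(seed, 1000L + b)))
        sc <- withStage("rf_importance",
            rfImportance(aug, y, nTrees = nTrees, mtry = mtry,
                         seed = mixSeed(seed, 2000L + b),
                         classWeighting = classWeighting))
        Wb <- knockoffStat(sc, featureNames = colnames(X))
        Wmat[b, ] <- Wb
        piMat[b, ] <- intermediatePValues(Wb)
        say("draw ", b, "/", B, ": OOB accuracy ",
            sprintf("%.3f", sc@oobAccuracy))
    }

    piBar <- withStage("quantile_aggregate", quantileAggregate(piMat, gamma = gamma))
    res <- withStage("bh_select", bhSelect(piBar, alpha = alpha))
    res@piB <- piMat
    res@W <- Wmat
    res@gamma <- gamma
    rep <- preprocessReport(xs)
    res@provenance <- list(
        t = t, B = as.integer(B), gamma = gamma, alpha = alpha,
        knnK = as.integer(knnK), nTrees = as.integer(nTrees),
        mtry = if (is.null(mtry)) round(sqrt(2 * p)) else as.integer(mtry),
        classWeighting = classWeighting, swap = swap,
        shrinkage = model@shrinkage, seed = as.integer(seed),
        nSamples = nrow(X), nMetabolites = p,
        kept = rep@keptMetabolites, dropped = rep@droppedMetabolites)
    say("selected ", length(res@selected), " of ", p, " metabolites")
    methods::validObject(res)
    res
}

#' Sweep the pipeline over several missingness thresholds
#'
#' Runs [runKnockoffPipeline()] once per threshold t and summarizes the
#' agreement of the resulting selections: the union (metabolites selected
#' at any t), the intersection (selected at every t) and pairwise overlap
#' counts -- the numbers behind a Venn-style comparison of thresholds. The
#' surviving metabolite set differs per t, so each run re-imputes and
#' re-standardizes its own table.
#'
#' By default every threshold gets an independent randomization (the
#' threshold is mixed into the seed), so cross-threshold overlaps are not
#' artifacts of shared knockoff noise; `sharedRandomness = TRUE` reuses
#' the identical master seed at every t for sensitivity analysis.
#'
#' @param x a [MetaboSet-class].
#' @param tValues thresholds to sweep; default `c(0, 60, 70, 80, 100)`.
#' @param sharedRandomness reuse the same seed at every t.
#' @param ... passed on to [runKnockoffPipeline()].
#' @param seed master seed.
#' @return A [SweepResult-class].
#' @export
sweepThresholds <- function(x, tValues = c(0, 60, 70, 80, 100),
                            sharedRandomness = FALSE, seed = 1L, ...) {
    if (length(tValues) == 0L) stop("'tValues' must be non-empty")
    results <- lapply(tValues, function(t) {
        tseed <- if (sharedRandomness) seed else mixSeed(seed, 100L + round(t))
        runKnockoffPipeline(x, t = t, seed = tseed, ...)
    })
    names(results) <- as.character(tValues)
    sel <- lapply(results, selectedMetabolites)
    uni <- sort(unique(unlist(sel)))
    inter <- if (length(sel)) sort(Reduce(intersect, sel)) else character()
    k <- length(sel)
    overlap <- matrix(0L, k, k, dimnames = list(names(sel), names(sel)))
    for (i in seq_len(k)) for (j in seq_len(k))
        overlap[i, j] <- length(intersect(sel[[i]], sel[[j]]))
    counts <- data.frame(t = tValues,
                         nSelected = vapply(sel, length, integer(1)))
    methods::new("SweepResult", results = results, union = uni,
                 intersection = inter, overlap = overlap, counts = counts)
}

#' Measure empirical FDR and power of the pipeline by simulation
#'
#' The evaluation harness: for each replicate, draw a synthetic dataset
#' with [simulateMetaboSet()], run the full pipeline, and score the
#' selection against the known ground truth with
#' \deqn{FDP = |selected \setminus signal| / \max(1, |selected|), \qquad
#'       power = |selected \cap signal| / \max(1, n_{signal}).}
#' Reports per-replicate values, means and Monte-Carlo standard errors.
#' When `nSignal = 0` the power is 0 by convention.
#'
#' @param nReplicates number of replicates (>= 2).
#' @param simArgs list of arguments for [simulateMetaboSet()]; the
#'   per-replicate seed is derived from `seed` and overrides any seed
#'   given here.
#' @param seed master seed.
#' @param ... pipeline settings passed to [runKnockoffPipeline()].
#' @return list with `perReplicate` (data.frame: replicate, nSelected,
#'   fdp, power), `meanFDP`, `seFDP`, `meanPower`, `sePower`.
#' @export
evaluateFdrPower <- function(nReplicates = 30L, simArgs = list(),
                             seed = 1L, ...) {
    nReplicates <- as.integer(nReplicates)
    if (nReplicates < 2L) stop("need at least 2 replicates")
    rows <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        sa <- simArgs
        sa$seed <- mixSeed(seed, r)
        x <- do.call(simulateMetaboSet, sa)
        res <- runKnockoffPipeline(x, seed = mixSeed(seed, 5000L + r), ...)
        truth <- groundTruth(x)$signalNames
        sel <- selectedMetabolites(res)
        fdp <- length(setdiff(sel, truth)) / max(1L, length(sel))
        pow <- if (length(truth) == 0L) 0 else
            length(intersect(sel, truth)) / length(truth)
        rows[[r]] <- data.frame(replicate = r, nSelected = length(sel),
                                fdp = fdp, power = pow)
    }
    per <- do.call(rbind, rows)
    se <- function(z) stats::sd(z) / sqrt(length(z))
    list(perReplicate = per,
         meanFDP = mean(per$fdp), seFDP = se(per$fdp),
         meanPower = mean(per$power), sePower = se(per$power))
}
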