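#' @include utils.R
NULL

# Correlation matrix implied by the requested structure, with positive-
# definiteness checks that name the offending parameter.
buildCorrelation <- function(p, correlation, rho, blockSize) {
    switch(correlation,
        independent = diag(p),
        ar1 = {
            if (abs(rho) >= 1)
                stop("'rho' must satisfy |rho| < 1 for an AR(1) structure")
            outer(seq_len(p), seq_len(p), function(i, j) rho^abs(i - j))
        },
        block = {
            if (blockSize < 1L) stop("'blockSize' must be a positive count")
            if (rho >= 1 || rho <= -1 / max(blockSize - 1, 1))
                stop("'rho' makes the block-equicorrelation matrix ",
                     "non-positive-definite (need -1/(blockSize-1) < rho < 1)")
            R <- diag(p)
            starts <- seq(1L, p, by = blockSize)
            for (st in starts) {
                idx <- st:min(st + blockSize - 1L, p)
                R[idx, idx] <- rho
                diag(R)[idx] <- 1
            }
            R
        },
        stop("unknown correlation structure: ", correlation))
}

#' Simulate a metabolomics-like feature table with known ground truth
#'
#' Generates an intensity table shaped like an untargeted LC-MS feature
#' table -- correlated positive intensities, per-metabolite missingness, a
#' per-sample class label -- together with the list of metabolites that are
#' truly class-associated, so that false discovery proportion and power of
#' any downstream selection can be measured exactly.
#'
#' A latent matrix is drawn class-wise from a multivariate normal with unit
#' variances and the configured correlation. Signal metabolites receive a
#' mean shift on the latent scale: class k is shifted by
#' `k * effectSize` within-class SDs, so consecutive classes are
#' `effectSize` apart and class 0 is the reference. With
#' `intensityScale = "lognormal"` the observed intensity is `exp(latent)`,
#' mimicking strictly positive MS peak intensities. Missing entries are then
#' introduced either completely at random (MCAR) or with probability
#' decreasing in the latent intensity through a logistic link
#' (`"intensity"`), the analogue of left-censoring near the detection
#' limit; in both mechanisms the per-metabolite expected missing fraction
#' equals `missingRate`.
#'
#' The defaults emulate a cohort-scale untargeted study: 546 samples in
#' three roughly equal classes, 100 named metabolites with AR(1)
#' correlation 0.5, lognormal intensities, a sparse set of 10 associated
#' metabolites, and 20% missingness.
#'
#' @param nSamples,nMetabolites table dimensions (samples, metabolites).
#' @param nClasses number of sample classes, >= 2; class sizes are equal
#'   with any remainder assigned to class 0.
#' @param nSignal number of truly class-associated metabolites, placed at a
#'   seeded random subset of columns; default `min(10, nMetabolites)`, a
#'   sparse signal set.
#' @param effectSize latent mean shift between consecutive classes, in
#'   within-class SD units; 0 gives a distributionally null table.
#' @param correlation `"independent"`, `"ar1"` or `"block"`.
#' @param rho correlation parameter (|rho| < 1 for AR(1); for blocks,
#'   -1/(blockSize-1) < rho < 1).
#' @param blockSize block width for `correlation = "block"`.
#' @param missingRate expected per-metabolite fraction of missing entries,
#'   in \[0, 1).
#' @param missingMechanism `"MCAR"` or `"intensity"` (logistic
#'   left-censoring in the latent value).
#' @param missingSteepness slope of the logistic link for
#'   `missingMechanism = "intensity"`; larger values concentrate
#'   missingness more sharply at low intensities.
#' @param intensityScale `"lognormal"` (exponentiated latent) or
#'   `"gaussian"` (latent used as-is).
#' @param classNames optional class label names (length `nClasses`).
#' @param seed RNG seed; the output is bit-reproducible given the seed.
#'
#' @return A [MetaboSet-class] whose `metadata()$groundTruth` holds
#'   `signalIndices`, `signalNames`, the K x p matrix of latent class
#'   means, and the full generating configuration.
#' @examples
#' x <- simulateMetaboSet(nSamples = 60, nMetabolites = 20, nSignal = 3,
#'                        missingRate = 0.1, seed = 7)
#' x
#' groundTruth(x)$signalNames
#' @export
simulateMetaboSet <- function(nSamples = 546L, nMetabolites = 100L,
                              nClasses = 3L, nSignal = NULL,
                              effectSize = 1.0,
                              correlation = c("ar1", "independent", "block"),
                              rho = 0.5, blockSize = 10L,
                              missingRate = 0.2,
                              missingMechanism = c("MCAR", "intensity"),
                              missingSteepness = 2,
                              intensityScale = c("lognormal", "gaussian"),
                              classNames = NULL, seed = 1L) {
    correlation <- match.arg(correlation)
    missingMechanism <- match.arg(missingMechanism)
    intensityScale <- match.arg(intensityScale)
    n <- as.integer(nSamples); p <- as.integer(nMetabolites)
    K <- as.integer(nClasses)
    if (n < 2L || p < 1L) stop("'nSamples'/'nMetabolites' must be positive counts")
    if (K < 2L) stop("'nClasses' must be at least 2")
    if (is.null(nSignal)) nSignal <- min(10L, p)
    if (nSignal < 0L || nSignal > p)
        stop("'nSignal' must satisfy 0 <= nSignal <= nMetabolites")
    if (effectSize < 0) stop("'effectSize' must be nonnegative")
    if (missingRate < 0 || missingRate >= 1)
        stop("'missingRate' must lie in [0, 1)")
    if (is.null(classNames))
        classNames <- paste0("G", seq_len(K) - 1L)
    if (length(classNames) != K) stop("'classNames' must have length nClasses")

    R <- buildCorrelation(p, correlation, rho, blockSize)
    cholR <- tryCatch(chol(R), error = function(e)
        stop("requested correlation structure ('rho' = ", rho,
             ") is not positive definite"))

    base <- n %/% K
    sizes <- rep(base, K)
    sizes[1] <- sizes[1] + n - base * K   # remainder to class 0
    y <- rep(seq_len(K) - 1L, times = sizes)

    out <- withSeed(seed, {
        signalIdx <- sort(sample.int(p)[seq_len(nSignal)])
        classMeans <- matrix(0, K, p,
                             dimnames = list(classNames, sprintf("M%03d", seq_len(p))))
        if (nSignal > 0L)
            for (k in seq_len(K))
                classMeans[k, signalIdx] <- (k - 1L) * effectSize
        latent <- matrix(stats::rnorm(n * p), n, p) %*% cholR
        latent <- latent + classMeans[y + 1L, , drop = FALSE]
        values <- if (intensityScale == "lognormal") exp(latent) else latent
        mask <- matrix(TRUE, n, p)
        if (missingRate > 0) {
            if (missingMechanism == "MCAR") {
                mask <- matrix(stats::runif(n * p) >= missingRate, n, p)
            } else {
                for (j in seq_len(p)) {
                    z <- latent[, j]
                    # intercept so the realized expected rate equals missingRate
                    a <- stats::uniroot(function(a)
                        mean(stats::plogis(a - missingSteepness * z)) - missingRate,
                        interval = c(-60, 60))$root
                    pr <- stats::plogis(a - missingSteepness * z)
                    mask[, j] <- stats::runif(n) >= pr
                }
            }
        }
        list(signalIdx = signalIdx, classMeans = classMeans,
             values = values, mask = mask)
    })

    metabNames <- sprintf("M%03d", seq_len(p))
    values <- out$values
    values[!out$mask] <- NA_real_
    dimnames(values) <- list(sprintf("S%03d", seq_len(n)), metabNames)
    gt <- list(
        signalIndices = out$signalIdx,
        signalNames = metabNames[out$signalIdx],
        classMeans = out$classMeans,
        config = list(nSamples = n, nMetabolites = p, nClasses = K,
                      nSignal = as.integer(nSignal), effectSize = effectSize,
                      correlation = correlation, rho = rho,
                      blockSize = as.integer(blockSize),
                      missingRate = missingRate,
                      missingMechanism = missingMechanism,
                      missingSteepness = missingSteepness,
                      intensityScale = intensityScale,
                      classNames = classNames, seed = as.integer(seed)))
    MetaboSet(values, classes = factor(classNames[y + 1L], levels = classNames),
              mask = out$mask, metadata = list(groundTruth = gt))
}
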