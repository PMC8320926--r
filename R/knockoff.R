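#' @include preprocess.R
NULL

#' Build a second-order knockoff model from known moments
#'
#' Given a mean vector and a positive-definite covariance, computes the
#' equi-correlated decorrelation vector s and the conditional pieces of the
#' Gaussian knockoff sampler: on the correlation scale
#' \eqn{s^{corr}_j = \min(2 \lambda_{min}(\Sigma^{corr}), 1)} for every j,
#' mapped back to the covariance scale by \eqn{s_j = s^{corr} \Sigma_{jj}}.
#' The conditional covariance
#' \eqn{V = 2\,diag(s) - diag(s) \Sigma^{-1} diag(s)} is symmetrized and,
#' if round-off pushes an eigenvalue below zero, floored to positive
#' semidefinite (with a warning when the floored mass exceeds 1e-8 of the
#' trace). Sampling uses the symmetric eigen square root of V, which is
#' defined for merely positive semidefinite V where a Cholesky factor is
#' not.
#'
#' @param mu length-p mean vector.
#' @param sigma p x p symmetric positive-definite covariance.
#' @param shrinkage shrinkage intensity to record in the model (for
#'   provenance; the moments are used as given).
#' @return A [KnockoffModel-class].
#' @seealso [fitKnockoffModel()] which estimates the moments from data.
#' @export
knockoffModelFromMoments <- function(mu, sigma, shrinkage = 0) {
    sigma <- as.matrix(sigma)
    p <- length(mu)
    if (p == 0L) stop("empty model: p = 0")
    if (!all(dim(sigma) == p)) stop("sigma must be p x p with p = length(mu)")
    if (max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma)))
        stop("sigma must be symmetric")
    sigma <- (sigma + t(sigma)) / 2
    dsd <- sqrt(diag(sigma))
    if (any(dsd <= 0)) stop("sigma must have positive diagonal")
    corrS <- sigma / tcrossprod(dsd)
    lamMin <- min(eigen(corrS, symmetric = TRUE, only.values = TRUE)$values)
    if (lamMin <= .Machine$double.eps^0.5)
        stop("sigma is numerically singular (min correlation eigenvalue ",
             format(lamMin), "); use stronger covariance regularization")
    sCorr <- min(2 * lamMin, 1)
    s <- sCorr * diag(sigma)
    sigInv <- chol2inv(chol(sigma))
    condCoef <- sigInv %*% diag(s, p)       # Sigma^{-1} diag(s)
    V <- 2 * diag(s, p) - diag(s, p) %*% condCoef
    V <- (V + t(V)) / 2
    ev <- eigen(V, symmetric = TRUE)
    neg <- pmin(ev$values, 0)
    if (-sum(neg) > 1e-8 * sum(abs(ev$values)))
        warning("conditional covariance needed eigenvalue flooring (",
                format(-sum(neg)), " of trace ", format(sum(abs(ev$values))), ")")
    lam <- pmax(ev$values, 0)
    V <- ev$vectors %*% (lam * t(ev$vectors))
    sqrtV <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
    methods::new("KnockoffModel", mu = as.numeric(mu), sigma = sigma,
                 s = as.numeric(s), condCoef = condCoef,
                 condCov = (V + t(V)) / 2, sqrtCondCov = (sqrtV + t(sqrtV)) / 2,
                 shrinkage = shrinkage)
}

#' Fit the Gaussian knockoff model of a standardized feature matrix
#'
#' Estimates the column means and a shrinkage-regularized covariance of a
#' complete (typically standardized) matrix and derives the equi-correlated
#' knockoff sampler from them. The covariance is the Ledoit-Wolf shrinkage
#' estimate toward a scaled identity (see [ledoitWolfCov()]); shrinkage
#' guarantees the inverse required by the conditional formulas even when p
#' is close to n.
#'
#' @param X complete numeric matrix, samples in rows; typically the
#'   standardized intensities, `intensityMatrix(standardizeIntensities(x))`.
#' @param shrinkage `NULL` for the automatic Ledoit-Wolf intensity, or a
#'   fixed value in \[0, 1\].
#' @return A [KnockoffModel-class].
#' @examples
#' x <- simulateMetaboSet(nSamples = 120, nMetabolites = 15,
#'                        missingRate = 0, seed = 9)
#' X <- intensityMatrix(standardizeIntensities(x))
#' fitKnockoffModel(X)
#' @export
fitKnockoffModel <- function(X, shrinkage = NULL) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) stop("no metabolites: p = 0")
    if (nrow(X) <= 2L) stop("need more than 2 samples")
    if (anyNA(X)) stop("X must be complete; impute first")
    lw <- ledoitWolfCov(X, shrinkage = shrinkage)
    knockoffModelFromMoments(colMeans(X), lw$sigma, shrinkage = lw$intensity)
}

#' Draw B independent knockoff copies
#'
#' Samples B knockoff matrices from the fitted conditional Gaussian,
#' \eqn{\tilde X^{(b)} = m(X) + E^{(b)} V^{1/2}} with
#' \eqn{m(X) = X - (X - 1\mu') \Sigma^{-1} diag(s)} and standard-normal
#' noise. The response never enters: the construction looks only at X, so
#' knockoffs are valid negative controls for any downstream classifier.
#' Copy b uses seed `xor(seed, b)`, making every copy individually
#' reproducible and the copies mutually independent given X.
#'
#' @param model a [KnockoffModel-class] fitted to (the moments of) `X`.
#' @param X the original complete matrix, samples in rows.
#' @param B number of copies (>= 1; 15 is the package-wide default used by
#'   [runKnockoffPipeline()]).
#' @param seed integer base seed.
#' @return A [KnockoffDraws-class].
#' @export
sampleKnockoffs <- function(model, X, B = 15L, seed = 1L) {
    stopifnot(methods::is(model, "KnockoffModel"))
    X <- as.matrix(X)
    p <- length(model@mu)
    if (ncol(X) != p)
        stop("X has ", ncol(X), " columns but the model was fitted for p = ", p)
    B <- as.integer(B)
    if (B < 1L) stop("B must be >= 1")
    n <- nrow(X)
    Xc <- sweep(X, 2L, model@mu)
    condMean <- X - Xc %*% model@condCoef
    seeds <- vapply(seq_len(B), function(b) bitwXor(as.integer(seed), b),
                    integer(1))
    copies <- lapply(seq_len(B), function(b) {
        E <- withSeed(seeds[b], matrix(stats::rnorm(n * p), n, p))
        K <- condMean + E %*% model@sqrtCondCov
        dimnames(K) <- dimnames(X)
        K
    })
    methods::new("KnockoffDraws", copies = copies, seeds = seeds, B = B)
}
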