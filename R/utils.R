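#' @include MetaboSet-methods.R
NULL

# Evaluate expr with a private RNG stream: the caller's .Random.seed is
# untouched.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Deterministic child-seed derivation; keeps results < 2^31 - 1 and distinct
# for distinct (seed, stream) pairs in the ranges used here.
mixSeed <- function(seed, stream) {
    as.integer((as.double(seed) %% 1009393 * 2117 + as.double(stream) * 7919 + 1) %%
               2147483629)
}

# Re-raise stage errors with the pipeline stage name attached.
withStage <- function(stage, expr) {
    withCallingHandlers(
        tryCatch(expr,
                 error = function(e)
                     stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)),
        warning = function(w) {
            warning("[stage: ", stage, "] ", conditionMessage(w), call. = FALSE)
            invokeRestart("muffleWarning")
        })
}

#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Shrinks the empirical covariance (denominator n - 1) toward the scaled
#' identity \eqn{\bar v I} with the analytic shrinkage intensity of Ledoit
#' and Wolf (2004). Guarantees a well-conditioned, positive-definite
#' estimate even when p approaches n, which the knockoff conditional
#' formulas require (they invert Sigma).
#'
#' @param X complete numeric matrix, samples in rows.
#' @param shrinkage `NULL` for the automatic intensity, or a fixed value in
#'   \[0, 1\] (0 = raw empirical covariance).
#' @return list with `sigma` (the estimate) and `intensity` (the shrinkage
#'   weight actually used).
#' @references Ledoit, O. and Wolf, M. (2004) A well-conditioned estimator
#'   for large-dimensional covariance matrices. JMVA 88:365-411.
#' @export
ledoitWolfCov <- function(X, shrinkage = NULL) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    if (n < 3L) stop("need at least 3 samples to estimate a covariance")
    Xc <- sweep(X, 2L, colMeans(X))
    S <- crossprod(Xc) / (n - 1)
    m <- sum(diag(S)) / p
    if (is.null(shrinkage)) {
        d2 <- sum((S - diag(m, p))^2) / p
        if (d2 < .Machine$double.eps) {
            rho <- 0
        } else {
            # sum_i ||x_i x_i' - S||_F^2 / n^2, per-feature normalized
            b2bar <- 0
            Sn <- crossprod(Xc) / n
            for (i in seq_len(n)) {
                xi <- Xc[i, ]
                b2bar <- b2bar + sum((tcrossprod(xi) - Sn)^2)
            }
            b2bar <- b2bar / (n^2 * p)
            rho <- min(b2bar / d2, 1)
        }
    } else {
        if (shrinkage < 0 || shrinkage > 1)
            stop("fixed shrinkage intensity must lie in [0, 1]")
        rho <- shrinkage
    }
    sigma <- rho * diag(m, p) + (1 - rho) * S
    dimnames(sigma) <- list(colnames(X), colnames(X))
    list(sigma = sigma, intensity = rho)
}
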