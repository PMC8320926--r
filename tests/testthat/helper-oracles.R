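# Independent brute-force oracles used to pin down the operative
# definitions. Deliberately naive (explicit loops / full enumeration) and
# kept free of any package internals.

bruteForceKnnImpute <- function(v, k) {
    n <- nrow(v); p <- ncol(v); out <- v
    for (i in seq_len(n)) for (j in seq_len(p)) if (is.na(v[i, j])) {
        d <- rep(Inf, n)
        for (i2 in seq_len(n)) if (i2 != i) {
            co <- which(!is.na(v[i, ]) & !is.na(v[i2, ]))
            if (length(co))
                d[i2] <- sqrt(sum((v[i, co] - v[i2, co])^2) / length(co))
        }
        ord <- order(d)
        ord <- ord[is.finite(d[ord])]
        donors <- ord[!is.na(v[ord, j])]
        out[i, j] <- if (length(donors) == 0L)
            mean(v[, j], na.rm = TRUE)
        else
            mean(v[donors[seq_len(min(k, length(donors)))], j])
    }
    out
}

bruteForceIntermediatePi <- function(W) {
    p <- length(W)
    out <- numeric(p)
    for (j in seq_len(p)) {
        if (W[j] <= 0) { out[j] <- 1; next }
        cnt <- 0L
        for (k in seq_len(p)) if (W[k] <= -W[j]) cnt <- cnt + 1L
        out[j] <- (1 + cnt) / p
    }
    out
}

bruteForceQuantileAgg <- function(piB, gamma) {
    out <- numeric(ncol(piB))
    for (j in seq_len(ncol(piB))) {
        v <- piB[, j]
        v <- v[order(v)]
        out[j] <- min(1, v[ceiling(gamma * length(v))] / gamma)
    }
    out
}

# Step-up rule by full enumeration of candidate ranks k.
bruteForceBhSelect <- function(p, alpha) {
    m <- length(p)
    ps <- sort(p)
    passing <- which(ps <= seq_len(m) * alpha / m)
    if (length(passing) == 0L) return(integer(0))
    thr <- ps[max(passing)]
    which(p <= thr)
}

# Multivariate normal draw via the Cholesky factor (test-local).
rmvn <- function(n, sigma) {
    p <- ncol(sigma)
    matrix(rnorm(n * p), n, p) %*% chol(sigma)
}

ar1Matrix <- function(p, rho) outer(seq_len(p), seq_len(p),
                                    function(i, j) rho^abs(i - j))

# Assemble an ImportanceScores object from given original/knockoff scores
# in unswapped column order.
makeScores <- function(Zorig, Zko, oob = 0.8) {
    p <- length(Zorig)
    methods::new("ImportanceScores",
        Z = stats::setNames(c(Zorig, Zko), paste0("V", seq_len(2 * p))),
        columnMap = data.frame(column = seq_len(2 * p),
                               feature = rep(seq_len(p), 2L),
                               role = rep(c("original", "knockoff"), each = p),
                               stringsAsFactors = FALSE),
        oobAccuracy = oob)
}
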