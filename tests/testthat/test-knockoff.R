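test_that("equi-correlated s has its closed form for simple covariances", {
    # 2x2 equicorrelation: eigenvalues 1 +/- rho, so s = min(2(1 - rho), 1)
    m <- knockoffModelFromMoments(c(0, 0), matrix(c(1, .6, .6, 1), 2))
    expect_equal(decorrelationVector(m), c(0.8, 0.8), tolerance = 1e-12)

    mI <- knockoffModelFromMoments(c(0, 0), diag(2))
    expect_equal(decorrelationVector(mI), c(1, 1), tolerance = 1e-12)
    # at Sigma = I, V = 2 diag(s) - diag(s)^2 = I
    expect_equal(mI@condCov, diag(2), tolerance = 1e-12)

    # non-unit variances: s maps back to the covariance scale
    m2 <- knockoffModelFromMoments(c(0, 0), diag(c(4, 9)))
    expect_equal(decorrelationVector(m2), c(4, 9), tolerance = 1e-12)
})

test_that("a model fitted on near-independent data approaches the identity solution", {
    set.seed(11)
    X <- scale(matrix(rnorm(4000 * 8), 4000, 8))
    m <- fitKnockoffModel(X)
    expect_true(all(abs(decorrelationVector(m) - 1) < 0.2))
    expect_lt(max(abs(m@condCov - diag(8))), 0.25)
    # conditional mean stays close to X itself when s ~ 1 and Sigma ~ I:
    # m(X) = X - (X - mu) Sigma^{-1} diag(s) ~ 1 mu'
    cm <- X - sweep(X, 2, m@mu) %*% m@condCoef
    expect_lt(max(abs(colMeans(cm))), 0.05)
})

test_that("the degenerate zero-noise model returns the conditional mean exactly", {
    p <- 3
    model <- methods::new("KnockoffModel", mu = rep(0, p), sigma = diag(p),
                          s = rep(0, p), condCoef = matrix(0, p, p),
                          condCov = matrix(0, p, p),
                          sqrtCondCov = matrix(0, p, p), shrinkage = 0)
    X <- matrix(rnorm(30), 10, p)
    d <- sampleKnockoffs(model, X, B = 2, seed = 1)
    # with Sigma = I and s = 0 the conditional mean is X itself
    expect_identical(knockoffCopies(d)[[1]], X)
    expect_identical(knockoffCopies(d)[[2]], X)
})

test_that("knockoff draws are reproducible per seed and independent across copies", {
    set.seed(2)
    X <- scale(rmvn(100, ar1Matrix(6, 0.4)))
    m <- fitKnockoffModel(X)
    d1 <- sampleKnockoffs(m, X, B = 3, seed = 10)
    d2 <- sampleKnockoffs(m, X, B = 3, seed = 10)
    d3 <- sampleKnockoffs(m, X, B = 3, seed = 11)
    expect_identical(knockoffCopies(d1), knockoffCopies(d2))
    expect_false(identical(knockoffCopies(d1)[[1]], knockoffCopies(d1)[[2]]))
    expect_false(identical(knockoffCopies(d1)[[1]], knockoffCopies(d3)[[1]]))
    expect_equal(d1@seeds, vapply(1:3, function(b) bitwXor(10L, b), integer(1)))
})

test_that("joint moments of [X, knockoff] satisfy the exchangeability conditions", {
    # known-Sigma check at moderate scale (the acceptance suite runs the
    # full-size version): cov([X, Xk]) -> [[S, S - diag(s)], [S - diag(s), S]]
    p <- 10; n <- 4000
    S <- ar1Matrix(p, 0.5)
    set.seed(33)
    X <- rmvn(n, S)
    m <- knockoffModelFromMoments(rep(0, p), S)
    Xk <- knockoffCopies(sampleKnockoffs(m, X, B = 1, seed = 7))[[1]]
    J <- cbind(X, Xk)
    G <- rbind(cbind(S, S - diag(m@s)), cbind(S - diag(m@s), S))
    Shat <- cov(J)
    se <- sqrt((outer(diag(G), diag(G)) + G^2) / n)
    z <- (Shat - G) / se
    M <- sum(upper.tri(z, diag = TRUE))
    bound <- qnorm(1 - 0.00135 / M)   # 3-SE per-entry level, family-adjusted
    expect_lt(max(abs(z)), bound)
    expect_lt(mean(abs(z)), 1.5)
})

test_that("null-feature W signs are symmetric", {
    # pure-null data: original and knockoff importances are exchangeable,
    # so sign(W) should be a fair coin across features and replicates
    signs <- integer(0)
    for (r in 1:6) {
        x <- simulateMetaboSet(nSamples = 80, nMetabolites = 15, nSignal = 0,
                               nClasses = 2, missingRate = 0,
                               intensityScale = "gaussian", seed = 100 + r)
        X <- intensityMatrix(standardizeIntensities(x))
        mod <- fitKnockoffModel(X)
        Xk <- knockoffCopies(sampleKnockoffs(mod, X, B = 1, seed = r))[[1]]
        aug <- augmentWithKnockoffs(X, Xk, swap = TRUE, seed = r)
        sc <- rfImportance(aug, classLabels(x), nTrees = 100, seed = r)
        W <- knockoffStat(sc)
        signs <- c(signs, sign(W[W != 0]))
    }
    pv <- binom.test(sum(signs > 0), length(signs))$p.value
    expect_gt(pv, 0.01)
})

test_that("stronger shrinkage never breaks positive semidefiniteness of V", {
    set.seed(4)
    X <- scale(rmvn(60, ar1Matrix(12, 0.7)))
    for (lam in c(0.05, 0.2, 0.5, 0.8, 1)) {
        m <- fitKnockoffModel(X, shrinkage = lam)
        ev <- eigen(m@condCov, symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), -1e-10)
    }
})

test_that("degenerate model inputs are rejected", {
    expect_error(knockoffModelFromMoments(numeric(0), matrix(0, 0, 0)), "p = 0")
    S <- matrix(c(1, 1, 1, 1), 2)  # singular
    expect_error(knockoffModelFromMoments(c(0, 0), S), "regularization")
    set.seed(9)
    X <- matrix(rnorm(40), 10, 4)
    m <- fitKnockoffModel(X)
    expect_error(sampleKnockoffs(m, X[, 1:3], B = 2, seed = 1), "p = 4")
    expect_error(sampleKnockoffs(m, X, B = 0, seed = 1), "B")
    expect_error(fitKnockoffModel(matrix(NA_real_, 10, 2)), "complete")
})
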