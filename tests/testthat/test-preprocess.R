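mkSet <- function(v, classes = NULL) {
    if (is.null(classes)) classes <- rep(c("a", "b"), length.out = nrow(v))
    MetaboSet(v, classes = classes)
}

test_that("the t% rule honours its edge cases and the observed-nonzero count", {
    v <- matrix(abs(rnorm(40)) + 1, 10, 4,
                dimnames = list(NULL, c("A", "B", "C", "D")))
    v[1, 1] <- NA              # A: one missing
    v[1:5, 3] <- NA            # C: observed in 5 of 10
    v[1:4, 4] <- NA            # D: observed in 6 of 10
    x <- mkSet(v)

    x0 <- tPercentFilter(x, 0)
    expect_identical(metaboliteNames(x0), c("A", "B", "C", "D"))
    expect_identical(intensityMatrix(x0), intensityMatrix(x))
    expect_length(preprocessReport(x0)@droppedMetabolites, 0)

    x100 <- tPercentFilter(x, 100)
    expect_identical(metaboliteNames(x100), "B")
    expect_setequal(preprocessReport(x100)@droppedMetabolites, c("A", "C", "D"))

    x60 <- tPercentFilter(x, 60)   # need >= ceiling(6) observed-nonzero
    expect_true("D" %in% metaboliteNames(x60))   # 6 observed: kept
    expect_false("C" %in% metaboliteNames(x60))  # 5 observed: dropped
})

test_that("a zero intensity counts as absent for the t% rule", {
    v <- matrix(1, 10, 2, dimnames = list(NULL, c("A", "B")))
    v[1:5, 2] <- 0
    x <- MetaboSet(v, classes = rep(c("a", "b"), 5))  # zeros observed in mask
    x60 <- tPercentFilter(x, 60)
    expect_identical(metaboliteNames(x60), "A")
})

test_that("the kept set shrinks monotonically in t", {
    x <- simulateMetaboSet(nSamples = 60, nMetabolites = 40, missingRate = 0.02,
                           seed = 3)
    kept <- lapply(c(20, 40, 60, 80, 100), function(t)
        metaboliteNames(tPercentFilter(x, t)))
    for (i in seq_len(length(kept) - 1L))
        expect_true(all(kept[[i + 1L]] %in% kept[[i]]))
})

test_that("out-of-range thresholds and empty survivors are errors", {
    x <- simulateMetaboSet(nSamples = 20, nMetabolites = 5, missingRate = 0.6,
                           seed = 2)
    expect_error(tPercentFilter(x, -5), "\\[0, 100\\]")
    expect_error(tPercentFilter(x, 101), "\\[0, 100\\]")
    expect_error(tPercentFilter(x, 100), "every metabolite")
})

test_that("KNN imputation is a no-op on complete tables and exact for identical samples", {
    x <- simulateMetaboSet(nSamples = 20, nMetabolites = 6, missingRate = 0,
                           seed = 5)
    expect_identical(intensityMatrix(knnImpute(x, 5)), intensityMatrix(x))

    v <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    v[2, 3] <- NA
    y <- knnImpute(mkSet(v), k = 2)
    expect_equal(intensityMatrix(y)[2, 3], 3)
    expect_true(all(observedMask(y)))
})

test_that("KNN imputation matches the brute-force neighbour oracle", {
    v <- matrix(rnorm(24), 6, 4,
                dimnames = list(sprintf("S%03d", 1:6), paste0("m", 1:4)))
    v[c(2, 21)] <- NA
    got <- intensityMatrix(knnImpute(mkSet(v), k = 2))
    expect_equal(got, bruteForceKnnImpute(v, 2), tolerance = 1e-12)

    for (seed in 1:5) {
        set.seed(seed)
        v <- matrix(rnorm(15 * 6), 15, 6,
                dimnames = list(sprintf("S%03d", 1:15), paste0("m", 1:6)))
        v[sample(length(v), 20)] <- NA
        x <- mkSet(v)
        got <- intensityMatrix(knnImpute(x, k = 3))
        expect_equal(got, bruteForceKnnImpute(v, 3), tolerance = 1e-12)
        # observed entries never altered
        expect_identical(got[!is.na(v)], v[!is.na(v)])
    }
})

test_that("imputation falls back to the column mean when no donor observes the column", {
    v <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
    v[1:3, 2] <- NA   # only sample 4 observes m2; imputing sample 4's other NAs fine
    v[4, 2] <- 5
    v[4, 3] <- NA
    y <- knnImpute(mkSet(v), k = 2)
    expect_equal(unname(intensityMatrix(y)[1:3, 2]), rep(5, 3))  # single donor everywhere
    expect_true(all(observedMask(y)))

    # true fallback: the only sample observing m2 shares no co-observed
    # coordinate with the sample being imputed, so it cannot be a neighbour
    w <- matrix(c(1, 2, NA,
                  NA, NA, 9), 3, 2,
                dimnames = list(NULL, c("m1", "m2")))
    z <- knnImpute(mkSet(w), k = 1)
    expect_equal(intensityMatrix(z)[1, 2], 9)  # column observed mean
})

test_that("a metabolite with no observed value is dropped with a warning before imputation", {
    v <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
    v[, 2] <- NA
    expect_warning(y <- knnImpute(mkSet(v), k = 2), "no observed value.*m2")
    expect_identical(metaboliteNames(y), c("m1", "m3"))
})

test_that("imputation neighbour count is validated", {
    x <- simulateMetaboSet(nSamples = 10, nMetabolites = 4, missingRate = 0.2,
                           seed = 4)
    expect_error(knnImpute(x, 0), "k")
    expect_error(knnImpute(x, 10), "k")
})

test_that("standardization gives exact zero mean / unit SD and is idempotent", {
    x <- simulateMetaboSet(nSamples = 50, nMetabolites = 10, missingRate = 0,
                           seed = 6)
    z <- standardizeIntensities(x)
    v <- intensityMatrix(z)
    expect_lt(max(abs(colMeans(v))), 1e-12)
    expect_lt(max(abs(apply(v, 2, sd) - 1)), 1e-12)
    z2 <- standardizeIntensities(z)
    expect_equal(intensityMatrix(z2), v, tolerance = 1e-10)
    rep <- preprocessReport(z)
    expect_length(rep@center, 10)
    expect_length(rep@scale, 10)
})

test_that("constant columns are dropped with a warning; missing entries are an error", {
    v <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
    v[, 2] <- 7
    expect_warning(z <- standardizeIntensities(mkSet(v)), "constant.*m2")
    expect_identical(metaboliteNames(z), c("m1", "m3"))

    v[1, 1] <- NA
    expect_error(standardizeIntensities(mkSet(v)), "missing")
})

test_that("on complete data the full preprocessing equals filter + standardize", {
    x <- simulateMetaboSet(nSamples = 40, nMetabolites = 12, missingRate = 0,
                           seed = 17)
    a <- standardizeIntensities(knnImpute(tPercentFilter(x, 70), k = 5))
    b <- standardizeIntensities(tPercentFilter(x, 70))
    expect_identical(intensityMatrix(a), intensityMatrix(b))
})
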