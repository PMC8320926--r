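test_that("knockoff-adjusted scores difference the matched pair", {
    s <- makeScores(c(0.30, 0.12, 0.05), c(0.10, 0.12, 0.20))
    W <- knockoffStat(s, featureNames = c("a", "b", "c"))
    expect_equal(W, c(a = 0.20, b = 0, c = -0.15), tolerance = 1e-12)

    # identical scores give an all-zero W
    s0 <- makeScores(c(0.1, 0.2), c(0.1, 0.2))
    expect_equal(unname(knockoffStat(s0)), c(0, 0))
})

test_that("the un-scrambled pairing drives W, not column position", {
    set.seed(12)
    n <- 120; p <- 8
    y <- factor(rep(c("u", "v"), length.out = n))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    X[, 3] <- as.integer(y) + rnorm(n, sd = 0.2)
    Xk <- matrix(rnorm(n * p), n, p)
    aug <- augmentWithKnockoffs(X, Xk, swap = TRUE, seed = 4)
    sc <- rfImportance(aug, y, nTrees = 150, seed = 6)
    W <- knockoffStat(sc, featureNames = colnames(X))
    # manual un-scramble straight from the recorded map
    cm <- sc@columnMap
    Z <- importanceScores(sc)
    manual <- vapply(seq_len(p), function(j) {
        zo <- Z[cm$column[cm$feature == j & cm$role == "original"]]
        zk <- Z[cm$column[cm$feature == j & cm$role == "knockoff"]]
        abs(zo) - abs(zk)
    }, numeric(1))
    expect_equal(unname(W), unname(manual), tolerance = 1e-12)
    expect_equal(unname(which.max(W)), 3L)
})

test_that("intermediate p-values reproduce the empirical-null counting rule", {
    expect_equal(unname(intermediatePValues(c(3, -1, 2))), c(1/3, 1, 1/3))
    expect_equal(unname(intermediatePValues(c(-2, 0, -0.5))), c(1, 1, 1))
    # boundary: W_k = -W_j counts through the <=
    expect_equal(unname(intermediatePValues(c(5, -5))), c(1, 1))
    expect_error(intermediatePValues(numeric(0)), "empty")
    expect_error(intermediatePValues(c(1, NA)), "finite")
})

test_that("intermediate p-values are monotone in W on the positive side", {
    set.seed(77)
    for (r in 1:20) {
        W <- round(rnorm(12), 2)
        pi <- intermediatePValues(W)
        pos <- which(W > 0)
        if (length(pos) >= 2) {
            o <- pos[order(W[pos], decreasing = TRUE)]
            expect_true(all(diff(pi[o]) >= 0))
        }
        expect_true(all(pi > 0 & pi <= 1))
    }
})

test_that("gamma-quantile aggregation follows the capped quantile formula", {
    expect_equal(unname(quantileAggregate(matrix(c(0.1, 0.2, 0.3), 3, 1))), 0.4)
    # single draw: doubles the p-value at gamma = 0.5, capped at 1
    expect_equal(unname(quantileAggregate(matrix(0.3, 1, 1))), 0.6)
    expect_equal(unname(quantileAggregate(matrix(0.9, 1, 1))), 1)
    expect_equal(unname(quantileAggregate(matrix(1, 5, 2))), c(1, 1))
    expect_error(quantileAggregate(matrix(0.5, 2, 2), gamma = 0), "gamma")
    expect_error(quantileAggregate(matrix(0.5, 2, 2), gamma = 1), "gamma")
})

test_that("aggregation is monotone per coordinate", {
    set.seed(3)
    A <- matrix(runif(5 * 4), 5, 4)
    B <- pmin(A + matrix(runif(20, 0, 0.2), 5, 4), 1)
    expect_true(all(quantileAggregate(B, 0.4) >= quantileAggregate(A, 0.4)))
})

test_that("BH step-up selects by the largest passing rank, ties inclusive", {
    r <- bhSelect(c(a = 0.001, b = 0.02, c = 0.8), alpha = 0.05)
    expect_setequal(selectedMetabolites(r), c("a", "b"))
    expect_equal(r@bhThreshold, 0.02)

    none <- bhSelect(c(a = 1, b = 1), alpha = 0.05)
    expect_length(selectedMetabolites(none), 0)
    expect_true(is.na(none@bhThreshold))

    # exactly alpha/m at rank 1 is selected (<= is inclusive)
    m <- 4
    edge <- bhSelect(c(w = 0.05 / m, x = 0.9, y = 0.95, z = 1), alpha = 0.05)
    expect_identical(selectedMetabolites(edge), "w")

    expect_error(bhSelect(numeric(0)), "empty")
    expect_error(bhSelect(c(0.1, 1.2)), "0, 1")
    expect_error(bhSelect(c(0.1), alpha = 0), "alpha")
})

test_that("selection results serialize to ranked TSV and JSON", {
    r <- bhSelect(c(a = 0.02, b = 0.8, c = 0.001), alpha = 0.05)
    tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
    df <- writeSelectionResult(r, jsonPath = js, tsvPath = tsv)
    expect_identical(df$metabolite, c("c", "a", "b"))
    back <- read.delim(tsv)
    expect_identical(back$metabolite, c("c", "a", "b"))
    expect_identical(back$selected, c(TRUE, TRUE, FALSE))
    j <- jsonlite::read_json(js, simplifyVector = TRUE)
    expect_setequal(j$selected, c("a", "c"))
    expect_equal(j$alpha, 0.05)
})

test_that("the three selection operations match brute force on random instances", {
    # a lighter randomized sweep; the acceptance suite runs the full 1000
    set.seed(2024)
    for (r in 1:200) {
        p <- sample(1:10, 1)
        W <- round(rnorm(p), 2)
        expect_equal(unname(intermediatePValues(W)), bruteForceIntermediatePi(W))
        B <- sample(1:5, 1)
        piB <- matrix(runif(B * p, 0.01, 1), B, p)
        gamma <- runif(1, 0.05, 0.95)
        expect_equal(unname(quantileAggregate(piB, gamma)),
                     bruteForceQuantileAgg(piB, gamma))
        pv <- round(runif(p), 2)
        pv[pv == 0] <- 0.01
        alpha <- runif(1, 0.01, 0.3)
        got <- bhSelect(pv, alpha = alpha)
        expect_setequal(selectedMetabolites(got),
                        paste0("F", seq_along(pv))[bruteForceBhSelect(pv, alpha)])
    }
})
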