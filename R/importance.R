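#' @include knockoff.R
NULL

#' Concatenate a feature matrix with one knockoff copy
#'
#' Builds the n x 2p augmented matrix on which the forest is trained. By
#' default the column positions of each (original, knockoff) pair are
#' swapped at random (seeded, recorded), so any position bias of the tree
#' builder cannot systematically favour originals; `swap = FALSE` restores
#' plain `[X | knockoff]` concatenation. Augmented columns get neutral
#' names, and the returned `columnMap` records which column carries
#' original metabolite j and which its knockoff, so importance scores can
#' be un-scrambled afterwards.
#'
#' @param X n x p original matrix.
#' @param Xk n x p knockoff copy of the same shape.
#' @param swap randomly swap within-pair column positions (default `TRUE`).
#' @param seed seed for the swap pattern.
#' @return list with `matrix` (n x 2p), `columnMap` (data.frame with
#'   `column`, `feature`, `role`), `swapped` (logical per pair) and
#'   `features` (the original column names).
#' @export
augmentWithKnockoffs <- function(X, Xk, swap = TRUE, seed = 1L) {
    X <- as.matrix(X); Xk <- as.matrix(Xk)
    if (!all(dim(X) == dim(Xk)))
        stop("X and its knockoff copy must have identical dimensions")
    p <- ncol(X)
    aug <- cbind(X, Xk)
    swapped <- if (swap)
        withSeed(seed, stats::runif(p) < 0.5)
    else rep(FALSE, p)
    for (j in which(swapped)) aug[, c(j, p + j)] <- aug[, c(p + j, j)]
    colnames(aug) <- paste0("V", seq_len(2L * p))
    role <- c(ifelse(swapped, "knockoff", "original"),
              ifelse(swapped, "original", "knockoff"))
    columnMap <- data.frame(column = seq_len(2L * p),
                            feature = rep(seq_len(p), 2L),
                            role = role, stringsAsFactors = FALSE)
    list(matrix = aug, columnMap = columnMap, swapped = swapped,
         features = colnames(X))
}

#' Random-forest OOB permutation importance of every augmented column
#'
#' Fits a classification random forest to the augmented matrix and scores
#' each of the 2p columns by Breiman's out-of-bag permutation importance:
#' for each tree, the drop in accuracy on its out-of-bag samples when the
#' column's values are randomly permuted, averaged over trees. The score
#' kept is the absolute value of that mean decrease, so Z >= 0. The forest
#' engine is \pkg{ranger} with unscaled permutation importance, which
#' implements exactly this per-tree OOB procedure; a single multiclass
#' forest is grown, with overall OOB accuracy as the metric.
#'
#' @param augmented the list returned by [augmentWithKnockoffs()].
#' @param y factor of class labels (>= 2 classes present).
#' @param nTrees number of trees (default 1000).
#' @param mtry candidate features per split; default
#'   `round(sqrt(ncol))`, the square root of the number of input columns
#'   (2p for an augmented matrix).
#' @param seed seed; the forest (and hence Z) is deterministic given it.
#' @param classWeighting `"none"` (default) or `"balanced"`
#'   (inverse-frequency class weights).
#' @return An [ImportanceScores-class].
#' @export
rfImportance <- function(augmented, y, nTrees = 1000L, mtry = NULL,
                         seed = 1L, classWeighting = c("none", "balanced")) {
    classWeighting <- match.arg(classWeighting)
    A <- augmented$matrix
    if (anyNA(A)) stop("augmented matrix must be complete")
    y <- droplevels(as.factor(y))
    if (length(y) != nrow(A))
        stop("length of y (", length(y), ") must match rows of the matrix (",
             nrow(A), ")")
    if (nlevels(y) < 2L) stop("y must contain at least 2 classes")
    if (nrow(A) < 10L) stop("need at least 10 samples to grow a forest")
    if (is.null(mtry)) mtry <- max(1L, round(sqrt(ncol(A))))
    if (mtry < 1L || mtry > ncol(A)) stop("mtry must lie in [1, ncol]")
    cw <- if (classWeighting == "balanced") {
        tab <- table(y)
        as.numeric(length(y) / (nlevels(y) * tab))
    } else NULL
    rf <- ranger::ranger(x = A, y = y, num.trees = as.integer(nTrees),
                         mtry = as.integer(mtry),
                         importance = "permutation",
                         scale.permutation.importance = FALSE,
                         class.weights = cw,
                         seed = as.integer(seed), num.threads = 1L)
    Z <- abs(rf$variable.importance)
    methods::new("ImportanceScores", Z = Z, columnMap = augmented$columnMap,
                 oobAccuracy = 1 - rf$prediction.error)
}
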