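#' @include importance.R
NULL

#' Knockoff-adjusted scores W from importance scores
#'
#' For every metabolite j, \eqn{W_j = |Z_{orig,j}| - |Z_{ko,j}|}: the
#' absolute importance of the original column minus that of its knockoff,
#' matched through the recorded column map (so the pair-position swap of
#' [augmentWithKnockoffs()] is undone). A large positive W is evidence
#' that metabolite j genuinely carries class information; for null
#' metabolites W is symmetric around zero by the exchangeability of the
#' knockoff construction.
#'
#' @param scores an [ImportanceScores-class].
#' @param featureNames optional names for the returned vector (in feature
#'   order); defaults to the augmented object's recorded feature names
#'   when available.
#' @return named numeric vector W of length p.
#' @export
knockoffStat <- function(scores, featureNames = NULL) {
    stopifnot(methods::is(scores, "ImportanceScores"))
    cm <- scores@columnMap
    p <- nrow(cm) / 2L
    origCol <- cm$column[cm$role == "original"][order(cm$feature[cm$role == "original"])]
    koCol <- cm$column[cm$role == "knockoff"][order(cm$feature[cm$role == "knockoff"])]
    if (length(origCol) != p || length(koCol) != p)
        stop("columnMap does not pair every original with one knockoff")
    W <- abs(scores@Z[origCol]) - abs(scores@Z[koCol])
    names(W) <- if (!is.null(featureNames)) featureNames else paste0("F", seq_len(p))
    W
}

#' Intermediate empirical p-values from knockoff-adjusted scores
#'
#' The empirical-null p-value of the aggregated-knockoff construction:
#' \deqn{\pi_j = (1 + \#\{k : W_k \le -W_j\}) / p \quad (W_j > 0), \qquad
#'       \pi_j = 1 \quad (W_j \le 0).}
#' Negative W values act as the empirical null distribution; a score with
#' no W below its negation gets the smallest attainable value 1/p. Zero or
#' negative evidence is mapped to 1 so it can never drive a discovery.
#'
#' @param W numeric vector of knockoff-adjusted scores (length p >= 1).
#' @return numeric vector of p-values in (0, 1], same names as `W`.
#' @examples
#' intermediatePValues(c(3, -1, 2))   # 1/3, 1, 1/3
#' @export
intermediatePValues <- function(W) {
    if (length(W) == 0L) stop("empty score vector")
    if (anyNA(W) || any(!is.finite(W))) stop("W must be finite")
    p <- length(W)
    pi <- vapply(W, function(w) {
        if (w <= 0) 1 else (1 + sum(W <= -w)) / p
    }, numeric(1))
    names(pi) <- names(W)
    pi
}

#' Gamma-quantile aggregation of per-draw p-values
#'
#' Combines the B intermediate p-values of each metabolite into one:
#' \deqn{\bar\pi_j = \min(1, \, q_\gamma(\{\pi_j^{(b)}\}) / \gamma),}
#' where \eqn{q_\gamma} is the lower empirical quantile, i.e. the order
#' statistic at index \eqn{\lceil \gamma B \rceil}. At the default
#' \eqn{\gamma = 0.5} this is twice the median, capped at 1 -- the price
#' paid for stabilizing the run-to-run randomness of a single knockoff
#' draw.
#'
#' @param piB B x p matrix of intermediate p-values (rows = draws).
#' @param gamma quantile level in (0, 1); default 0.5.
#' @return length-p vector of aggregated p-values in (0, 1].
#' @examples
#' quantileAggregate(matrix(c(0.1, 0.2, 0.3), 3, 1), gamma = 0.5)  # 0.4
#' @export
quantileAggregate <- function(piB, gamma = 0.5) {
    piB <- as.matrix(piB)
    if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)")
    B <- nrow(piB)
    if (B < 1L) stop("need at least one draw")
    idx <- ceiling(gamma * B)
    piBar <- apply(piB, 2L, function(col) sort(col)[idx] / gamma)
    out <- pmin(piBar, 1)
    names(out) <- colnames(piB)
    out
}

#' Benjamini-Hochberg step-up selection
#'
#' Applies the BH step-up rule to the aggregated p-values: with
#' \eqn{\bar\pi_{(1)} \le \dots \le \bar\pi_{(m)}},
#' \eqn{k^* = \max\{k : \bar\pi_{(k)} \le k\alpha/m\}} and every
#' metabolite with \eqn{\bar\pi_j \le \bar\pi_{(k^*)}} is selected (ties
#' at the threshold included). The denominator m is the number of
#' metabolites that survived the t% filter -- the set actually tested.
#' Implemented through [stats::p.adjust()] ("BH"), whose adjusted values
#' under alpha reproduce the step-up rule exactly.
#'
#' @param piBar named numeric vector of aggregated p-values in (0, 1].
#' @param alpha FDR control level in (0, 1); default 0.05.
#' @param names optional metabolite names (default `names(piBar)`).
#' @return A [SelectionResult-class] (with empty W/piB slots; the pipeline
#'   fills them).
#' @examples
#' r <- bhSelect(c(a = 0.001, b = 0.02, c = 0.8), alpha = 0.05)
#' selectedMetabolites(r)
#' @export
bhSelect <- function(piBar, alpha = 0.05, names = NULL) {
    if (length(piBar) == 0L) stop("empty p-value vector")
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
    if (any(piBar <= 0 | piBar > 1)) stop("p-values must lie in (0, 1]")
    if (is.null(names)) names <- names(piBar)
    if (is.null(names)) names <- paste0("F", seq_along(piBar))
    names(piBar) <- names
    adj <- stats::p.adjust(piBar, method = "BH")
    sel <- adj <= alpha
    thr <- if (any(sel)) max(piBar[sel]) else NA_real_
    methods::new("SelectionResult",
                 selected = names[sel], alpha = alpha, bhThreshold = thr,
                 piBar = piBar)
}

#' Write a SelectionResult to disk
#'
#' Serializes a selection as JSON (selection, threshold, provenance) and,
#' optionally, as a ranked TSV with one row per metabolite: name, mean
#' knockoff-adjusted score over draws, aggregated p-value and the selected
#' flag, ordered by aggregated p-value.
#'
#' @param result a [SelectionResult-class].
#' @param jsonPath path of the JSON output (or `NULL` to skip).
#' @param tsvPath path of the ranked TSV output (or `NULL` to skip).
#' @return Invisibly, the ranked data.frame.
#' @export
writeSelectionResult <- function(result, jsonPath = NULL, tsvPath = NULL) {
    stopifnot(methods::is(result, "SelectionResult"))
    meanW <- if (nrow(result@W)) colMeans(result@W) else
        rep(NA_real_, length(result@piBar))
    df <- data.frame(metabolite = names(result@piBar),
                     meanW = as.numeric(meanW),
                     piBar = as.numeric(result@piBar),
                     selected = names(result@piBar) %in% result@selected,
                     stringsAsFactors = FALSE)
    df <- df[order(df$piBar, -df$meanW), ]
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(selected = result@selected, alpha = result@alpha,
                 bhThreshold = result@bhThreshold,
                 piBar = as.list(result@piBar),
                 provenance = result@provenance),
            jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(tsvPath))
        utils::write.table(df, tsvPath, sep = "\t", row.names = FALSE,
                           quote = FALSE)
    invisible(df)
}
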