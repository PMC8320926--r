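#' @include simulate.R
NULL

guessSep <- function(path) {
    if (grepl("\\.(tsv|txt)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a delimited metabolomics feature table
#'
#' Parses a CSV/TSV export of an intensity table (such as a Metabolomics
#' Workbench named-metabolite table) into a [MetaboSet-class]. Two layouts
#' are supported: samples as rows (first column = sample id, one column of
#' class labels, remaining columns metabolites) or its transpose,
#' metabolites as rows (first column = metabolite name, remaining column
#' headers sample ids, one row -- named like `classColumn` -- carrying the
#' class labels).
#'
#' @param path file path (UTF-8, header row required).
#' @param classColumn name of the column (or row, for
#'   `orientation = "metabolites"`) holding the class labels.
#' @param orientation `"samples"` if rows are samples, `"metabolites"` if
#'   rows are metabolites.
#' @param missingCodes character values flagged as missing (after
#'   whitespace trimming). Defaults to blank, `NA`, `NaN`.
#' @param zeroIsMissing if `TRUE` (default), a literal 0 intensity is
#'   treated as a missing measurement -- the convention implied by
#'   zero-filled exports, where absent peaks are coded 0. Set to `FALSE`
#'   when 0 is a genuine measurement.
#' @param sep field separator; guessed from the extension by default.
#'
#' @return A [MetaboSet-class].
#' @details A cell that is neither numeric nor a missing code is an error
#'   reporting the offending row and column; duplicated metabolite names or
#'   sample ids and a missing class column are errors as well.
#' @examples
#' x <- simulateMetaboSet(nSamples = 10, nMetabolites = 4, seed = 3)
#' f <- tempfile(fileext = ".csv")
#' writeFeatureTable(x, f)
#' y <- readFeatureTable(f)
#' all.equal(intensityMatrix(x), intensityMatrix(y))
#' @export
readFeatureTable <- function(path, classColumn = "class",
                             orientation = c("samples", "metabolites"),
                             missingCodes = c("", "NA", "NaN"),
                             zeroIsMissing = TRUE, sep = NULL) {
    orientation <- match.arg(orientation)
    if (is.null(sep)) sep <- guessSep(path)
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE,
                             quote = "\"", comment.char = "")
    if (ncol(raw) < 2L) stop("feature table needs at least two columns")

    if (orientation == "samples") {
        sampleIds <- trimws(raw[[1L]])
        # keep the raw header: data.frame subsetting silently uniquifies
        # duplicated metabolite names before they can be reported
        bodyNames <- colnames(raw)[-1L]
        ci <- which(bodyNames == classColumn)
        if (length(ci) == 0L)
            stop("class column '", classColumn, "' not found in ", path)
        if (length(ci) > 1L)
            stop("class column '", classColumn, "' appears more than once in ", path)
        body <- raw[, -1L, drop = FALSE]
        classes <- trimws(as.character(body[[ci]]))
        cells <- as.matrix(body[, -ci, drop = FALSE])
        metabNames <- bodyNames[-ci]
        colnames(cells) <- metabNames
        rowIds <- sampleIds; colIds <- metabNames
    } else {
        metabNamesAll <- trimws(raw[[1L]])
        sampleIds <- colnames(raw)[-1L]
        classRow <- which(metabNamesAll == classColumn)
        if (length(classRow) != 1L)
            stop("class row '", classColumn, "' not found in ", path)
        classes <- trimws(unlist(raw[classRow, -1L], use.names = FALSE))
        keep <- setdiff(seq_len(nrow(raw)), classRow)
        metabNames <- metabNamesAll[keep]
        cells <- t(as.matrix(raw[keep, -1L, drop = FALSE]))
        rowIds <- sampleIds; colIds <- metabNames
    }

    if (anyDuplicated(colIds))
        stop("duplicate metabolite names: ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    if (anyDuplicated(rowIds))
        stop("duplicate sample ids: ",
             paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))

    cells <- trimws(cells)
    miss <- is.na(cells) | cells %in% missingCodes
    num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad <- which(!miss & is.na(num), arr.ind = TRUE)
    if (nrow(bad)) {
        b <- bad[1L, ]
        stop("non-numeric cell '", cells[b[1L], b[2L]], "' at sample '",
             rowIds[b[1L]], "', metabolite '", colIds[b[2L]], "'")
    }
    if (zeroIsMissing) miss <- miss | (!miss & num == 0)
    num[miss] <- NA_real_
    dimnames(num) <- list(rowIds, colIds)
    MetaboSet(num, classes = classes, mask = !miss)
}

#' Write a MetaboSet as a delimited feature table
#'
#' Writes the table in the layout [readFeatureTable()] reads back
#' (samples as rows by default), with missing entries as empty cells.
#' For simulated data a JSON sidecar (`<path>.json`) records the ground
#' truth and the full generating configuration, so a written dataset is
#' self-describing.
#'
#' @param x a [MetaboSet-class].
#' @param path output file; extension `.tsv`/`.txt` selects tab separation.
#' @param orientation `"samples"` (rows are samples) or `"metabolites"`.
#' @param classColumn header used for the class label column/row.
#' @param sidecar write the JSON ground-truth sidecar when ground truth is
#'   present (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(x, path, orientation = c("samples", "metabolites"),
                              classColumn = "class", sidecar = TRUE) {
    orientation <- match.arg(orientation)
    sep <- guessSep(path)
    v <- intensityMatrix(x)
    fmt <- function(z) ifelse(is.na(z), "", format(z, digits = 17, trim = TRUE,
                                                   scientific = FALSE))
    if (orientation == "samples") {
        df <- data.frame(sample_id = sampleIds(x),
                         class = as.character(classLabels(x)),
                         apply(v, 2L, fmt),
                         check.names = FALSE, stringsAsFactors = FALSE)
        names(df)[2L] <- classColumn
    } else {
        mat <- t(apply(v, 2L, fmt))
        df <- data.frame(metabolite = c(classColumn, metaboliteNames(x)),
                         rbind(as.character(classLabels(x)), mat),
                         check.names = FALSE, stringsAsFactors = FALSE)
        names(df)[-1L] <- sampleIds(x)
    }
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    gt <- groundTruth(x)
    if (sidecar && !is.null(gt)) {
        gtOut <- gt
        gtOut$classMeans <- NULL   # recoverable from config; keep sidecar lean
        jsonlite::write_json(gtOut, paste0(path, ".json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}
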