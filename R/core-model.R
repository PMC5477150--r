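#' Compute standard retention times (St_R)
#'
#' The standard retention time of a compound is the arithmetic mean of
#' its measured retention times over a panel of chromatographic columns
#' run under one fixed elution program.  It plays the role of the
#' consensus abscissa for all calibration fits in the package.
#'
#' A column with any missing compound cannot enter the average; such
#' columns must be dropped from \code{included} (they are never imputed).
#'
#' @param table a \linkS4class{RetentionTable}.
#' @param included character, the column identifiers to average over;
#'   defaults to all columns of \code{table}.
#' @return a \linkS4class{StandardRetention}.
#' @examples
#' tab <- paridisRetention()
#' stR(computeStR(tab))
#' @export
computeStR <- function(table, included = columnIds(table)) {
    stopifnot(is(table, "RetentionTable"))
    if (length(included) == 0L)
        stop("the set of included columns must not be empty")
    missingCols <- setdiff(included, columnIds(table))
    if (length(missingCols))
        stop("unknown column identifiers: ",
             paste(missingCols, collapse = ", "))
    m <- retentionTimes(table)[, included, drop = FALSE]
    incomplete <- colnames(m)[colSums(is.na(m)) > 0L]
    if (length(incomplete))
        stop("included column(s) with missing compounds must be excluded ",
             "before St_R computation: ", paste(incomplete, collapse = ", "))
    .StandardRetention(stR = rowMeans(m), columnsUsed = as.character(included))
}

#' @rdname lctrs-generics
#' @export
setMethod("stR", "StandardRetention", function(object, ...) object@stR)

#' @rdname lctrs-generics
#' @export
setMethod("columnsUsed", "StandardRetention",
    function(object, ...) object@columnsUsed)

#' @rdname lctrs-generics
#' @export
setMethod("nColumnsUsed", "StandardRetention",
    function(object, ...) length(object@columnsUsed))

#' @rdname lctrs-generics
#' @export
setMethod("compounds", "StandardRetention",
    function(object, ...) names(object@stR))

setMethod("show", "StandardRetention", function(object) {
    cat("StandardRetention over", nColumnsUsed(object), "columns\n")
    print(round(object@stR, 3))
})

#' Construct a StandardRetention from known values
#'
#' Used for externally supplied consensus values (e.g. a published St_R
#' table) rather than values computed from a panel.
#'
#' @param stR named numeric, St_R per compound (minutes).
#' @param columnsUsed character, identifiers of the columns behind the
#'   values.
#' @return a \linkS4class{StandardRetention}.
#' @export
standardRetention <- function(stR, columnsUsed) {
    .StandardRetention(stR = stR, columnsUsed = as.character(columnsUsed))
}

#' Deviation between measured and predicted retention time
#'
#' The absolute deviation (in minutes) used throughout the package to
#' score predictions: symmetric, non-negative, zero iff the two times
#' coincide.
#'
#' @param tMea,tPre measured and predicted retention times (minutes);
#'   vectorized.
#' @return numeric, |tMea - tPre|.
#' @examples
#' deltaTR(22.898, 23.481)  # 0.583
#' @export
deltaTR <- function(tMea, tPre) {
    if (any(!is.finite(tMea)) || any(!is.finite(tPre)))
        stop("retention times must be finite")
    abs(tMea - tPre)
}

#' Define a reference-compound pair
#'
#' Orders the two compounds by St_R (the member with the smaller St_R
#' becomes \code{first}) and computes the coverage of t_R: the fraction
#' of the panel's retention span bracketed by the pair.
#'
#' @param strt a \linkS4class{StandardRetention} covering at least the
#'   two compounds.
#' @param first,second compound identifiers.
#' @return a \linkS4class{ReferencePair}.
#' @seealso [coverageOfTR()]
#' @export
referencePair <- function(strt, first, second) {
    st <- stR(strt)
    for (cc in c(first, second))
        if (!cc %in% names(st))
            stop("compound not in the St_R profile: ", cc)
    if (identical(first, second))
        stop("the two reference compounds must differ")
    if (st[[first]] > st[[second]]) {
        tmp <- first; first <- second; second <- tmp
    }
    if (st[[first]] == st[[second]])
        stop("degenerate reference pair: the two compounds co-elute on the ",
             "St_R scale")
    cov <- .coverageValue(st[[first]], st[[second]], st)
    if (cov == 0)
        stop("invalid reference pair: zero coverage")
    .ReferencePair(first = first, second = second, coverage = cov)
}

.coverageValue <- function(st1, st2, stAll) {
    span <- max(stAll) - min(stAll)
    if (span <= 0)
        stop("degenerate St_R profile: all compounds co-elute")
    abs(st2 - st1) / span
}

#' Coverage of t_R of a reference pair
#'
#' Coverage = (St_R(second) - St_R(first)) / (St_R(last) - St_R(first
#' compound)): the fraction of the panel's full St_R span bracketed by
#' the two reference compounds.  It equals 1 when the pair consists of
#' the first- and last-eluting compounds, and 0 for a co-eluting
#' (invalid) pair.  High coverage (0.8-1.0) gives the most accurate
#' two-point calibrations.
#'
#' @param pair a \linkS4class{ReferencePair}, or a character vector of
#'   two compound identifiers.
#' @param strt a \linkS4class{StandardRetention} (at least two
#'   compounds).
#' @return the coverage fraction in [0, 1].
#' @export
coverageOfTR <- function(pair, strt) {
    st <- stR(strt)
    if (length(st) < 2L)
        stop("coverage needs at least two compounds")
    if (is.character(pair)) {
        stopifnot(length(pair) == 2L)
        .coverageValue(st[[pair[1L]]], st[[pair[2L]]], st)
    } else {
        .coverageValue(st[[pair@first]], st[[pair@second]], st)
    }
}

#' @rdname lctrs-generics
#' @export
setMethod("tRCoverage", "ReferencePair", function(object, ...)
    object@coverage)

setMethod("show", "ReferencePair", function(object) {
    cat(sprintf("ReferencePair: '%s' -> '%s' (coverage of t_R: %.4f)\n",
                object@first, object@second, object@coverage))
})

#' Calibrated retention (CR) of an analyte
#'
#' The dimensionless position of an analyte between the two reference
#' compounds on the St_R axis: CR = (St_R(analyte) - St_R(first)) /
#' (St_R(second) - St_R(first)).  CR of the first reference is 0 and of
#' the second 1; interpolating the two references' measured times with CR
#' is mathematically identical to the two-point calibration prediction.
#' CR unifies the calibration with the relative-retention method, which
#' is the special case with the origin (or the dead time) as first
#' anchor.
#'
#' @param strt a \linkS4class{StandardRetention}.
#' @param pair a \linkS4class{ReferencePair}.
#' @param analyte compound identifier(s) present in \code{strt}.
#' @return named numeric, CR per analyte.
#' @examples
#' st <- standardRetention(c(A = 19.803, B = 22.110, C = 33.035), "col")
#' pr <- referencePair(st, "A", "C")
#' calibratedRetention(st, pr, "B")
#' @export
calibratedRetention <- function(strt, pair, analyte) {
    st <- stR(strt)
    bad <- setdiff(analyte, names(st))
    if (length(bad))
        stop("analyte not in the St_R profile: ", paste(bad, collapse = ", "))
    denom <- st[[pair@second]] - st[[pair@first]]
    if (denom == 0)
        stop("degenerate reference pair")
    (st[analyte] - st[[pair@first]]) / denom
}
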