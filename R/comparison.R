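#' Construct a relative-retention model
#'
#' @param rr named numeric, relative retentions (dimensionless); must
#'   include the reference compound with value 1.
#' @param reference the reference compound identifier.
#' @param t0 dead time in minutes (hold-up time of an unretained probe);
#'   \code{NA} when not measured.
#' @param adjusted whether \code{rr} are dead-time corrected values.
#' @return an \linkS4class{RRModel}.
#' @export
rrModel <- function(rr, reference, t0 = NA_real_, adjusted = FALSE) {
    .RRModel(reference = reference, rr = rr, t0 = t0, adjusted = adjusted)
}

setMethod("show", "RRModel", function(object) {
    cat(sprintf("RRModel (%s), reference: '%s'",
                if (object@adjusted) "adjusted" else "unadjusted",
                object@reference))
    if (!is.na(object@t0)) cat(sprintf(", t0 = %.3f min", object@t0))
    cat("\n")
    print(round(object@rr, 3))
})

#' Derive an adjusted RR model from St_R and a dead time
#'
#' Adjusted relative retentions are ratios of dead-time-corrected
#' retention: RR_adj(i) = (St_R(i) - t0) / (St_R(ref) - t0).
#'
#' @param strt a \linkS4class{StandardRetention}.
#' @param reference the reference compound identifier.
#' @param t0 dead time in minutes; must be smaller than every St_R.
#' @return an adjusted \linkS4class{RRModel}.
#' @export
adjustedRRModel <- function(strt, reference, t0) {
    st <- stR(strt)
    if (!reference %in% names(st))
        stop("reference compound not in the St_R profile: ", reference)
    if (is.na(t0)) stop("adjusted RR needs a dead time t0")
    if (t0 >= min(st))
        stop("dead time must be smaller than every retention time")
    rrModel((st - t0) / (st[[reference]] - t0), reference, t0 = t0,
            adjusted = TRUE)
}

#' Predict retention times with the RR method
#'
#' The RR method anchors every compound to a single reference compound
#' measured on the target column.  Unadjusted: t_pre = RR * t_ref (a
#' one-point calibration through the origin).  Adjusted: t_pre = t0 +
#' RR_adj * (t_ref - t0), i.e. the same one-point calibration on
#' dead-time-corrected retention.
#'
#' @param model an \linkS4class{RRModel}.
#' @param refTMea measured retention time of the reference compound on
#'   the target column (minutes).
#' @param analytes compounds to predict; defaults to all compounds of
#'   the model.
#' @return named numeric of predicted retention times.
#' @examples
#' m <- rrModel(c(A = 0.729, B = 1), "B")
#' rrPredict(m, 27.161, "A")  # 19.800
#' @export
rrPredict <- function(model, refTMea, analytes = names(model@rr)) {
    .assertScalarNumber(refTMea, "refTMea")
    if (refTMea <= 0)
        stop("the reference measured time must be positive")
    bad <- setdiff(analytes, names(model@rr))
    if (length(bad))
        stop("no RR value for: ", paste(bad, collapse = ", "))
    if (model@adjusted) {
        if (is.na(model@t0))
            stop("adjusted prediction requires a dead time t0")
        if (model@t0 >= refTMea)
            stop("dead time must be smaller than the reference retention time")
        model@t0 + model@rr[analytes] * (refTMea - model@t0)
    } else {
        model@rr[analytes] * refTMea
    }
}

#' Summarize a panel of deviations into a method report
#'
#' Computes the maximum and mean deviation over all (compound, column)
#' cells of a deviation table and counts the positive columns: columns
#' on which every pending compound's deviation is within the acceptance
#' limit t_R_L.  The chromatographic-resolution clause of the full
#' positive-column definition needs raw chromatograms and is flagged as
#' not evaluated.
#'
#' @param deltaTable numeric matrix of absolute deviations (minutes),
#'   pending compounds in rows, columns of the panel in columns.
#' @param tRLimit acceptance limit in minutes.
#' @param method method tag (see \linkS4class{MethodReport}).
#' @return a \linkS4class{MethodReport}.
#' @export
evaluateMethod <- function(deltaTable, tRLimit,
                           method = c("rr_unadjusted", "rr_adjusted",
                                      "lctrs_two_point",
                                      "lctrs_multi_point")) {
    method <- match.arg(method)
    if (!is.matrix(deltaTable) || length(deltaTable) == 0L)
        stop("empty deviation panel")
    if (anyNA(deltaTable) || any(deltaTable < 0))
        stop("deviations must be non-negative and complete")
    .MethodReport(method = method,
                  maxDeltaTR = max(deltaTable),
                  meanDeltaTR = mean(deltaTable),
                  positiveColumns =
                      sum(apply(deltaTable, 2L, max) <= tRLimit),
                  deltaTable = deltaTable,
                  tRLimit = tRLimit,
                  notes = paste("positive-column count checks the",
                                "deviation criterion only; the",
                                "chromatographic-resolution clause is",
                                "not evaluated"))
}

setMethod("show", "MethodReport", function(object) {
    cat(sprintf(
        "MethodReport '%s': max dTR %.3f min, mean dTR %.3f min, %d/%d positive columns (tRL = %.2f)\n",
        object@method, object@maxDeltaTR, object@meanDeltaTR,
        object@positiveColumns, ncol(object@deltaTable), object@tRLimit))
})

#' Compare the calibration and RR methods over a whole panel
#'
#' Each panel column in turn plays the target column: the reference
#' compounds' measured times are taken from the table, and all four
#' methods predict the remaining (pending) compounds, whose known
#' measured times score the prediction.  Pending compounds are all
#' non-reference compounds of each method (the RR methods share one
#' reference compound; the calibration methods share the reference
#' pair).  Methods: unadjusted RR, adjusted RR (requires a dead time),
#' two-point calibration, and multiple-point regression over references
#' plus analytes.
#'
#' @param table a complete \linkS4class{RetentionTable}.
#' @param rrmod an \linkS4class{RRModel} with unadjusted RR values; its
#'   \code{t0} (or the \code{t0} argument) enables the adjusted variant.
#' @param pair a \linkS4class{ReferencePair} for the calibration
#'   methods.
#' @param strt a \linkS4class{StandardRetention}; computed from all
#'   columns when \code{NULL}.
#' @param cfg a \linkS4class{MatchConfig} (its \code{tRLimit} defines
#'   positive columns).
#' @param t0 dead time in minutes, overriding \code{rrmod@t0}.
#' @return a list with one \linkS4class{MethodReport} per method
#'   (\code{rr_unadjusted}, \code{rr_adjusted}, \code{lctrs_two_point},
#'   \code{lctrs_multi_point}) plus \code{ranking}, a data.frame of the
#'   four methods sorted by mean deviation.
#' @export
compareAll <- function(table, rrmod, pair, strt = NULL,
                       cfg = matchConfig(), t0 = rrmod@t0) {
    m <- retentionTimes(table)
    if (anyNA(m))
        stop("the method comparison needs a complete panel")
    if (is.null(strt)) strt <- computeStR(table)
    st <- stR(strt)
    cols <- colnames(m)
    if (is.na(t0))
        stop("the adjusted RR method needs a dead time t0; supply it in ",
             "the RR model or via the t0 argument")

    ref1 <- rrmod@reference
    pendRR <- setdiff(rownames(m), ref1)
    predU <- outer(rrmod@rr[pendRR], m[ref1, ])
    dU <- abs(predU - m[pendRR, , drop = FALSE])

    adj <- adjustedRRModel(strt, ref1, t0)
    predA <- t0 + outer(adj@rr[pendRR], m[ref1, ] - t0)
    dA <- abs(predA - m[pendRR, , drop = FALSE])

    refs <- c(pair@first, pair@second)
    pendL <- setdiff(rownames(m), refs)
    d2 <- vapply(cols, function(cc) {
        line <- fitTwoPoint(st[refs], m[refs, cc])
        abs(m[pendL, cc] - predict(line, st[pendL]))
    }, numeric(length(pendL)))
    dM <- vapply(cols, function(cc) {
        fit <- .ols(st[rownames(m)], m[, cc])
        abs(m[pendL, cc] - (fit$slope * st[pendL] + fit$intercept))
    }, numeric(length(pendL)))
    d2 <- matrix(d2, length(pendL), length(cols),
                 dimnames = list(pendL, cols))
    dM <- matrix(dM, length(pendL), length(cols),
                 dimnames = list(pendL, cols))

    lim <- cfg@tRLimit
    reports <- list(
        rr_unadjusted = evaluateMethod(dU, lim, "rr_unadjusted"),
        rr_adjusted = evaluateMethod(dA, lim, "rr_adjusted"),
        lctrs_two_point = evaluateMethod(d2, lim, "lctrs_two_point"),
        lctrs_multi_point = evaluateMethod(dM, lim, "lctrs_multi_point"))
    ranking <- methodSummary(reports)
    ranking <- ranking[order(ranking$mean_dtr), , drop = FALSE]
    rownames(ranking) <- NULL
    c(reports, list(ranking = ranking))
}

#' Summary table of method reports
#'
#' @param reports a list of \linkS4class{MethodReport} objects.
#' @return a data.frame with columns \code{method}, \code{max_dtr},
#'   \code{mean_dtr}, \code{positive_columns}.
#' @export
methodSummary <- function(reports) {
    reports <- Filter(function(x) is(x, "MethodReport"), reports)
    data.frame(
        method = vapply(reports, function(x) x@method, ""),
        max_dtr = vapply(reports, function(x) x@maxDeltaTR, numeric(1)),
        mean_dtr = vapply(reports, function(x) x@meanDeltaTR, numeric(1)),
        positive_columns = vapply(reports, function(x)
            as.integer(x@positiveColumns), integer(1)),
        stringsAsFactors = FALSE, row.names = NULL)
}
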