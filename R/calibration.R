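#' Construct a CalibrationLine directly
#'
#' Mostly useful for tests and for re-using published coefficients; fits
#' are normally obtained with [fitTwoPoint()] or [validateMultipoint()].
#'
#' @param slope dimensionless slope.
#' @param intercept intercept in minutes.
#' @param r Pearson correlation of the fitted points (\code{NA} when
#'   undefined, e.g. for two-point fits).
#' @param method \code{"two_point"} or \code{"least_squares"}.
#' @return a \linkS4class{CalibrationLine}.
#' @export
calibrationLine <- function(slope, intercept, r = NA_real_,
                            method = c("least_squares", "two_point")) {
    .CalibrationLine(slope = slope, intercept = intercept, r = r,
                     method = match.arg(method))
}

#' @rdname lctrs-generics
#' @export
setMethod("slope", "CalibrationLine", function(object, ...) object@slope)

#' @rdname lctrs-generics
#' @export
setMethod("intercept", "CalibrationLine",
    function(object, ...) object@intercept)

#' @rdname lctrs-generics
#' @export
setMethod("corrCoef", "CalibrationLine", function(object, ...) object@r)

setMethod("show", "CalibrationLine", function(object) {
    cat(sprintf("CalibrationLine (%s): tR = %.6f * StR %+.6f",
                object@method, object@slope, object@intercept))
    if (!is.na(object@r)) cat(sprintf("  (r = %.6f)", object@r))
    cat("\n")
})

#' Two-point calibration fit
#'
#' The unique line through the two reference points (St_R, t_R_mea):
#' the reference compounds' standard retention times on the abscissa and
#' their measured times on the target column on the ordinate.  The line
#' interpolates both inputs exactly.
#'
#' @param refStR numeric(2), St_R of the two reference compounds
#'   (minutes); must be distinct.
#' @param refTMea numeric(2), their measured retention times on the
#'   target column (minutes), in the same order.
#' @return a \linkS4class{CalibrationLine} with \code{method =
#'   "two_point"}.
#' @examples
#' fitTwoPoint(c(19.803, 33.035), c(21.014, 35.170))
#' @export
fitTwoPoint <- function(refStR, refTMea) {
    stopifnot(length(refStR) == 2L, length(refTMea) == 2L)
    if (any(!is.finite(refStR)) || any(!is.finite(refTMea)))
        stop("reference points must be finite")
    if (refStR[1L] == refStR[2L])
        stop("degenerate reference pair: identical St_R values")
    refStR <- unname(refStR)
    refTMea <- unname(refTMea)
    a <- (refTMea[2L] - refTMea[1L]) / (refStR[2L] - refStR[1L])
    b <- refTMea[1L] - a * refStR[1L]
    .CalibrationLine(slope = a, intercept = b, r = NA_real_,
                     method = "two_point")
}

#' @describeIn fitTwoPoint predict retention times from a calibration
#'   line: \code{t_R_pre = slope * St_R + intercept}.
#' @param object a \linkS4class{CalibrationLine}.
#' @param stRValues numeric, St_R values to map (minutes).
#' @param ... ignored.
#' @export
setMethod("predict", "CalibrationLine",
    function(object, stRValues, ...) {
        object@slope * stRValues + object@intercept
    })

#' Predicted retention times for a set of analytes
#'
#' Applies a calibration line to the analytes' St_R values and wraps the
#' result in a \linkS4class{PredictionSet}.
#'
#' @param line a \linkS4class{CalibrationLine}.
#' @param strt a \linkS4class{StandardRetention}, or a named numeric of
#'   St_R values.
#' @param analytes compound identifiers to predict; defaults to all
#'   compounds of \code{strt}.
#' @param stage stage tag for the result.
#' @return a \linkS4class{PredictionSet}.
#' @export
predictRetention <- function(line, strt, analytes = NULL,
                             stage = c("two_point", "multi_point")) {
    st <- if (is(strt, "StandardRetention")) stR(strt) else strt
    if (is.null(analytes)) analytes <- names(st)
    bad <- setdiff(analytes, names(st))
    if (length(bad))
        stop("no St_R value for: ", paste(bad, collapse = ", "))
    .PredictionSet(predicted = predict(line, st[analytes]),
                   line = line, stage = match.arg(stage))
}

#' @rdname lctrs-generics
#' @export
setMethod("predicted", "PredictionSet", function(object, ...)
    object@predicted)

setMethod("show", "PredictionSet", function(object) {
    cat("PredictionSet (", object@stage, " stage)\n", sep = "")
    print(round(object@predicted, 3))
})

#' Multiple-point regression validation
#'
#' After the two-point assignment, the measured times of the reference
#' compounds and of every assigned analyte are regressed on their St_R
#' values by ordinary least squares (a stepwise refinement of the
#' two-point line).  New predictions and deviations are computed from
#' this line while the peak assignment itself is kept fixed.  The
#' prediction is a success iff every analyte was assigned a peak and
#' every refitted deviation is within the acceptance limit t_R_L.
#'
#' With only the two reference points supplied the least-squares line
#' coincides with the two-point interpolant.
#'
#' @param matched a \linkS4class{MatchResult} from [matchPeaks()].
#' @param refStR named numeric(2), St_R of the reference compounds.
#' @param refTMea numeric(2), their measured times on the target column.
#' @param strt a \linkS4class{StandardRetention} (used for analyte St_R
#'   values; may be omitted because \code{matched} already carries them).
#' @param cfg a \linkS4class{MatchConfig}; defaults to the config stored
#'   in \code{matched}.
#' @return a \linkS4class{MatchResult} with stage \code{"multi_point"}.
#' @export
validateMultipoint <- function(matched, refStR, refTMea, strt = NULL,
                               cfg = NULL) {
    stopifnot(is(matched, "MatchResult"))
    if (is.null(cfg)) cfg <- matched@config
    res <- matched@results
    assigned <- !is.na(res$tRMea)
    x <- c(refStR, res$stR[assigned])
    y <- c(refTMea, res$tRMea[assigned])
    if (length(unique(x)) < 2L)
        stop("multiple-point regression needs at least two distinct ",
             "St_R values")
    fit <- .ols(x, y)
    line <- .CalibrationLine(slope = fit$slope, intercept = fit$intercept,
                             r = fit$r, method = "least_squares")
    res$tRPreMultiPoint <- predict(line, res$stR)
    res$deltaTRMultiPoint <- ifelse(assigned,
                                    abs(res$tRMea - res$tRPreMultiPoint),
                                    NA_real_)
    lim <- .effectiveLimits(cfg, res$analyte)$limit
    res$withinLimit <- !is.na(res$deltaTRMultiPoint) &
        res$deltaTRMultiPoint <= lim
    .MatchResult(results = res, twoPointLine = matched@twoPointLine,
                 multiPointLine = line, stage = "multi_point",
                 success = all(assigned) && all(res$withinLimit),
                 config = cfg)
}

#' Run the full two-reference calibration pipeline on one column
#'
#' Composes the pipeline for a single target column: two-point fit
#' through the reference compounds, prediction of the analytes, window
#' matching of observed peaks (with the sequential rule for close
#' predictions), and multiple-point regression validation.  Both stages'
#' predictions are retained in the result.
#'
#' @param x a \linkS4class{RetentionTable} (St_R is computed from all its
#'   complete columns) or a \linkS4class{StandardRetention}.
#' @param pair a \linkS4class{ReferencePair}.
#' @param refTMea numeric(2), measured retention times of the pair
#'   (first, second) on the target column, from reference-substance
#'   injections.
#' @param peaks a \linkS4class{PeakList} (or numeric vector) of observed
#'   sample peaks on the target column.
#' @param cfg a \linkS4class{MatchConfig}.
#' @param analytes compounds to predict; defaults to every compound of
#'   the St_R profile except the two references.
#' @return a \linkS4class{MatchResult} with stage \code{"multi_point"}.
#' @examples
#' tab <- paridisRetention()
#' st <- computeStR(tab)
#' pr <- referencePair(st, "Chonglou saponin VII", "Chonglou saponin I")
#' runLCTRS(st, pr, refTMea = c(21.014, 35.170),
#'          peaks = c(21.014, 22.898, 32.679, 35.170),
#'          cfg = matchConfig(tRWindow = 0.6, tRLimit = 0.5))
#' @export
runLCTRS <- function(x, pair, refTMea, peaks, cfg = matchConfig(),
                     analytes = NULL) {
    strt <- if (is(x, "RetentionTable")) {
        complete <- columnIds(x)[colSums(is.na(retentionTimes(x))) == 0L]
        computeStR(x, complete)
    } else x
    stopifnot(is(strt, "StandardRetention"), is(pair, "ReferencePair"))
    if (length(refTMea) != 2L)
        stop("refTMea must hold the two reference compounds' measured times")
    if (is.null(analytes))
        analytes <- setdiff(compounds(strt), c(pair@first, pair@second))
    if (length(analytes) == 0L)
        stop("no analytes to predict")
    st <- stR(strt)
    line2 <- fitTwoPoint(st[c(pair@first, pair@second)], refTMea)
    .stageLog("two_point",
              sprintf("tR = %.10g * StR %+.10g", line2@slope,
                      line2@intercept))
    preds <- predictRetention(line2, strt, analytes, stage = "two_point")
    mr <- matchPeaks(preds, peaks, cfg)
    vr <- validateMultipoint(mr, refStR = st[c(pair@first, pair@second)],
                             refTMea = refTMea, strt = strt, cfg = cfg)
    .stageLog("multi_point",
              sprintf("tR = %.10g * StR %+.10g (r = %.10g)",
                      vr@multiPointLine@slope, vr@multiPointLine@intercept,
                      vr@multiPointLine@r))
    vr
}

#' @rdname lctrs-generics
#' @export
setMethod("matchSuccess", "MatchResult", function(object, ...)
    object@success)

#' @rdname lctrs-generics
#' @export
setMethod("deltaTRValues", "MatchResult", function(object, ...) {
    r <- object@results
    d <- if (object@stage == "multi_point") r$deltaTRMultiPoint
         else r$deltaTRTwoPoint
    stats::setNames(d, r$analyte)
})

setMethod("show", "MatchResult", function(object) {
    cat("MatchResult (stage: ", object@stage, ")\n", sep = "")
    r <- object@results
    print(data.frame(analyte = r$analyte,
                     tRPre = round(if (object@stage == "multi_point")
                                       r$tRPreMultiPoint
                                   else r$tRPreTwoPoint, 3),
                     tRMea = round(r$tRMea, 3),
                     deltaTR = round(if (object@stage == "multi_point")
                                         r$deltaTRMultiPoint
                                     else r$deltaTRTwoPoint, 3),
                     row.names = NULL))
    cat(if (isTRUE(object@success)) "prediction: success\n"
        else "prediction: failure\n")
})
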