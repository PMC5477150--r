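#' RetentionTable: a compound-by-column matrix of retention times
#'
#' A \code{SummarizedExperiment} whose \code{"tR"} assay holds measured
#' retention times (minutes) of K compounds (rows) on N chromatographic
#' columns (columns), all acquired under one fixed elution program.  An
#' optional \code{"sd"} assay holds per-cell standard deviations from
#' replicate injections.  Cells may be \code{NA} (compound not measured on
#' that column); such columns must be excluded before St_R computation.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [RetentionTable()], [computeStR()], [readRetentionTable()]
#' @exportClass RetentionTable
.RetentionTable <- setClass("RetentionTable", contains = "SummarizedExperiment")

setValidity("RetentionTable", function(object) {
    msg <- character(0)
    if (!"tR" %in% assayNames(object))
        msg <- c(msg, "assay 'tR' is required")
    else {
        m <- assay(object, "tR")
        if (!is.numeric(m))
            msg <- c(msg, "assay 'tR' must be numeric")
        else if (any(m[is.finite(m)] <= 0))
            msg <- c(msg, "all retention times must be strictly positive")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "compound identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "column identifiers (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' StandardRetention: consensus retention times over a column panel
#'
#' Per-compound standard retention time St_R (minutes), the arithmetic
#' mean of the measured retention times over the columns used, together
#' with the identities of those columns.
#'
#' @slot stR named numeric, St_R per compound (minutes).
#' @slot columnsUsed character, the column identifiers averaged over.
#' @exportClass StandardRetention
.StandardRetention <- setClass("StandardRetention",
    slots = c(stR = "numeric", columnsUsed = "character"))

setValidity("StandardRetention", function(object) {
    msg <- character(0)
    if (length(object@columnsUsed) < 1L)
        msg <- c(msg, "at least one column must be used (n >= 1)")
    if (is.null(names(object@stR)) || anyDuplicated(names(object@stR)))
        msg <- c(msg, "stR must be named by unique compound identifiers")
    if (any(!is.finite(object@stR)) || any(object@stR <= 0))
        msg <- c(msg, "St_R values must be finite and positive")
    if (length(msg)) msg else TRUE
})

#' CalibrationLine: an affine map from St_R to retention time
#'
#' Holds the slope a (dimensionless), intercept b (minutes) and, for
#' least-squares fits on three or more points, the Pearson correlation r
#' of the fitted points.  For two-point fits r is undefined (the line
#' interpolates both points) and stored as \code{NA}.
#'
#' @slot slope numeric(1), dimensionless.
#' @slot intercept numeric(1), minutes.
#' @slot r numeric(1), Pearson correlation; \code{NA} when undefined.
#' @slot method character(1), \code{"two_point"} or \code{"least_squares"}.
#' @exportClass CalibrationLine
.CalibrationLine <- setClass("CalibrationLine",
    slots = c(slope = "numeric", intercept = "numeric",
              r = "numeric", method = "character"))

setValidity("CalibrationLine", function(object) {
    msg <- character(0)
    if (length(object@slope) != 1L || !is.finite(object@slope))
        msg <- c(msg, "slope must be a single finite number")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msg <- c(msg, "intercept must be a single finite number")
    if (length(object@r) != 1L || (!is.na(object@r) && abs(object@r) > 1 + 1e-12))
        msg <- c(msg, "|r| must be <= 1 when defined")
    if (!object@method %in% c("two_point", "least_squares"))
        msg <- c(msg, "method must be 'two_point' or 'least_squares'")
    if (length(msg)) msg else TRUE
})

#' ReferencePair: the two reference compounds of a calibration
#'
#' The first member elutes earlier on the St_R scale than the second.
#' Coverage is the fraction of the panel's St_R span bracketed by the two
#' references; pairs with coverage 0.8-1.0 are preferred.
#'
#' @slot first,second character(1), compound identifiers.
#' @slot coverage numeric(1), fraction in [0, 1].
#' @exportClass ReferencePair
.ReferencePair <- setClass("ReferencePair",
    slots = c(first = "character", second = "character", coverage = "numeric"))

setValidity("ReferencePair", function(object) {
    msg <- character(0)
    if (identical(object@first, object@second))
        msg <- c(msg, "the two reference compounds must differ")
    if (length(object@coverage) != 1L || is.na(object@coverage) ||
        object@coverage < 0 || object@coverage > 1 + 1e-12)
        msg <- c(msg, "coverage must be a fraction in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' MatchConfig: window, limit and series-gap settings for peak matching
#'
#' \code{tRWindow} (t_R_W) is the half-width of the search window around a
#' predicted time; \code{tRLimit} (t_R_L) is the acceptance limit applied
#' after multiple-point validation; \code{seriesGap} is the closeness
#' threshold below which predictions are considered a peak series for
#' sequential matching.  The window is set larger than the limit.
#' Per-compound overrides of window and limit are allowed.
#'
#' @slot tRWindow,tRLimit,seriesGap numeric(1), minutes.
#' @slot overrides data.frame with columns \code{compound},
#'   \code{tRWindow}, \code{tRLimit} (\code{NA} = use the global value).
#' @exportClass MatchConfig
.MatchConfig <- setClass("MatchConfig",
    slots = c(tRWindow = "numeric", tRLimit = "numeric",
              seriesGap = "numeric", overrides = "data.frame"))

setValidity("MatchConfig", function(object) {
    msg <- character(0)
    if (!(object@tRLimit > 0))
        msg <- c(msg, "tRLimit must be > 0")
    if (object@tRWindow < object@tRLimit)
        msg <- c(msg, "tRWindow must be >= tRLimit (window wider than limit)")
    if (!(object@seriesGap > 0))
        msg <- c(msg, "seriesGap must be > 0")
    ov <- object@overrides
    if (nrow(ov) &&
        !all(c("compound", "tRWindow", "tRLimit") %in% colnames(ov)))
        msg <- c(msg, "overrides needs columns compound, tRWindow, tRLimit")
    if (length(msg)) msg else TRUE
})

#' PeakList: observed peak retention times in one chromatogram
#'
#' Strictly increasing retention times (minutes) of the peaks observed in
#' one sample chromatogram on one target column, with optional labels.
#'
#' @slot peaks numeric, strictly increasing, minutes.
#' @slot labels character, same length as \code{peaks} or empty.
#' @exportClass PeakList
.PeakList <- setClass("PeakList",
    slots = c(peaks = "numeric", labels = "character"))

setValidity("PeakList", function(object) {
    msg <- character(0)
    p <- object@peaks
    if (any(!is.finite(p)) || any(p <= 0))
        msg <- c(msg, "peak retention times must be finite and positive")
    if (length(p) > 1L && any(diff(p) <= 0))
        msg <- c(msg, "peak retention times must be strictly increasing")
    if (length(object@labels) && length(object@labels) != length(p))
        msg <- c(msg, "labels must match the number of peaks")
    if (length(msg)) msg else TRUE
})

#' PredictionSet: predicted retention times on a target column
#'
#' @slot predicted named numeric, predicted retention times (minutes).
#' @slot line the \linkS4class{CalibrationLine} used.
#' @slot stage character(1), \code{"two_point"} or \code{"multi_point"}.
#' @exportClass PredictionSet
.PredictionSet <- setClass("PredictionSet",
    slots = c(predicted = "numeric", line = "CalibrationLine",
              stage = "character"))

setValidity("PredictionSet", function(object) {
    msg <- character(0)
    if (any(!is.finite(object@predicted)))
        msg <- c(msg, "predictions must be finite")
    if (is.null(names(object@predicted)))
        msg <- c(msg, "predictions must be named by analyte")
    if (!object@stage %in% c("two_point", "multi_point"))
        msg <- c(msg, "stage must be 'two_point' or 'multi_point'")
    if (length(msg)) msg else TRUE
})

setClassUnion("CalibrationLine_OR_NULL", c("CalibrationLine", "NULL"))

#' MatchResult: peak assignment and validation outcome for one column
#'
#' Per-analyte predictions, assigned observed peaks and deviations for one
#' target column.  The \code{results} data frame has one row per analyte
#' with columns \code{analyte}, \code{stR}, \code{tRPreTwoPoint},
#' \code{tRMea}, \code{deltaTRTwoPoint}, \code{withinWindow},
#' \code{tRPreMultiPoint}, \code{deltaTRMultiPoint}, \code{withinLimit}
#' (the multi-point columns are \code{NA} until validation).  After the
#' two-point stage \code{success} means every analyte found a peak inside
#' its window; after multi-point validation it additionally requires every
#' deviation to be within the acceptance limit t_R_L.
#'
#' @slot results data.frame, one row per analyte (see above).
#' @slot twoPointLine,multiPointLine the calibration lines of the two
#'   stages (\code{multiPointLine} is \code{NULL} before validation).
#' @slot stage character(1), \code{"two_point"} or \code{"multi_point"}.
#' @slot success logical(1).
#' @slot config the \linkS4class{MatchConfig} used.
#' @exportClass MatchResult
.MatchResult <- setClass("MatchResult",
    slots = c(results = "data.frame", twoPointLine = "CalibrationLine",
              multiPointLine = "CalibrationLine_OR_NULL",
              stage = "character", success = "logical",
              config = "MatchConfig"))

setValidity("MatchResult", function(object) {
    msg <- character(0)
    need <- c("analyte", "stR", "tRPreTwoPoint", "tRMea", "deltaTRTwoPoint",
              "withinWindow", "tRPreMultiPoint", "deltaTRMultiPoint",
              "withinLimit")
    if (!all(need %in% colnames(object@results)))
        msg <- c(msg, paste("results must have columns:",
                            paste(need, collapse = ", ")))
    else {
        r <- object@results
        if (any(is.na(r$tRMea) != is.na(r$deltaTRTwoPoint)))
            msg <- c(msg, "deltaTR must be present iff a peak was assigned")
    }
    if (!object@stage %in% c("two_point", "multi_point"))
        msg <- c(msg, "stage must be 'two_point' or 'multi_point'")
    if (length(msg)) msg else TRUE
})

#' ColumnFit: least-squares fit of one column's retention times on St_R
#'
#' @slot column character(1), column identifier.
#' @slot line the fitted \linkS4class{CalibrationLine}.
#' @slot residuals named numeric, per-compound absolute residuals
#'   |t_R_mea - fitted| (minutes).
#' @exportClass ColumnFit
.ColumnFit <- setClass("ColumnFit",
    slots = c(column = "character", line = "CalibrationLine",
              residuals = "numeric"))

#' ExclusionReport: outlier columns and compounds of a panel
#'
#' @slot excludedColumns data.frame with columns \code{column},
#'   \code{reason}.
#' @slot excludedCompounds data.frame with columns \code{compound},
#'   \code{reason}.
#' @slot retainedColumns,retainedCompounds character.
#' @slot finalStR \linkS4class{StandardRetention} recomputed from the
#'   retained columns and compounds.
#' @slot thresholds list, the r / residual / fraction thresholds applied.
#' @exportClass ExclusionReport
.ExclusionReport <- setClass("ExclusionReport",
    slots = c(excludedColumns = "data.frame",
              excludedCompounds = "data.frame",
              retainedColumns = "character",
              retainedCompounds = "character",
              finalStR = "StandardRetention",
              thresholds = "list"))

#' SubsampleSummary: deviation as a function of panel size
#'
#' One row per subset size k: the mean and standard deviation, over random
#' non-replicate column subsets, of the mean absolute deviation between
#' measured times and the multiple-point line fitted against the subset
#' St_R.
#'
#' @slot summary data.frame with columns \code{k}, \code{nDraws},
#'   \code{meanDeltaTR}, \code{sdDeltaTR}.
#' @slot seed integer(1), the seed the draws were generated under.
#' @exportClass SubsampleSummary
.SubsampleSummary <- setClass("SubsampleSummary",
    slots = c(summary = "data.frame", seed = "integer"))

#' RRModel: the relative-retention benchmark model
#'
#' Per-compound relative retentions anchored to one reference compound.
#' In the unadjusted form RR multiplies the reference's measured time; in
#' the adjusted form retention is first corrected by the dead time t0
#' (hold-up time of an unretained probe).
#'
#' @slot reference character(1), reference compound identifier.
#' @slot rr named numeric, dimensionless; \code{rr[reference] == 1}.
#' @slot t0 numeric(1), dead time in minutes (\code{NA} when unknown).
#' @slot adjusted logical(1), whether \code{rr} are dead-time corrected.
#' @exportClass RRModel
.RRModel <- setClass("RRModel",
    slots = c(reference = "character", rr = "numeric",
              t0 = "numeric", adjusted = "logical"))

setValidity("RRModel", function(object) {
    msg <- character(0)
    if (is.null(names(object@rr)) || !object@reference %in% names(object@rr))
        msg <- c(msg, "rr must be named and include the reference compound")
    else if (abs(object@rr[[object@reference]] - 1) > 1e-9)
        msg <- c(msg, "RR of the reference compound must equal 1")
    if (any(!is.finite(object@rr)) || any(object@rr <= 0))
        msg <- c(msg, "RR values must be finite and positive")
    if (!is.na(object@t0) && object@t0 < 0)
        msg <- c(msg, "dead time t0 must be >= 0")
    if (object@adjusted && is.na(object@t0))
        msg <- c(msg, "an adjusted RR model requires a dead time t0")
    if (length(msg)) msg else TRUE
})

#' MethodReport: panel-level deviation statistics of one method
#'
#' @slot method character(1), one of \code{"rr_unadjusted"},
#'   \code{"rr_adjusted"}, \code{"lctrs_two_point"},
#'   \code{"lctrs_multi_point"}.
#' @slot maxDeltaTR,meanDeltaTR numeric(1), minutes.
#' @slot positiveColumns integer(1), columns on which every pending
#'   compound's deviation is within the acceptance limit.
#' @slot deltaTable matrix, per-compound (rows) per-column deviations.
#' @slot tRLimit numeric(1), the limit used for the positive count.
#' @slot notes character, caveats (e.g. the chromatographic-resolution
#'   clause of the positive-column definition is not evaluated here).
#' @exportClass MethodReport
.MethodReport <- setClass("MethodReport",
    slots = c(method = "character", maxDeltaTR = "numeric",
              meanDeltaTR = "numeric", positiveColumns = "integer",
              deltaTable = "matrix", tRLimit = "numeric",
              notes = "character"))

setValidity("MethodReport", function(object) {
    msg <- character(0)
    if (!object@method %in% c("rr_unadjusted", "rr_adjusted",
                              "lctrs_two_point", "lctrs_multi_point"))
        msg <- c(msg, "unknown method tag")
    if (object@meanDeltaTR < 0 ||
        object@maxDeltaTR < object@meanDeltaTR - 1e-12)
        msg <- c(msg, "max >= mean >= 0 must hold")
    if (object@positiveColumns > ncol(object@deltaTable))
        msg <- c(msg, "positive count cannot exceed the number of columns")
    if (length(msg)) msg else TRUE
})

#' PanelSpec: a stated world for synthetic retention panels
#'
#' Each synthetic column j is an affine image of the true St_R profile:
#' t_R[i, j] = a_j * StR_true[i] + b_j + noise, with slopes and intercepts
#' drawn from normal distributions and i.i.d. Gaussian measurement noise.
#' Outliers can be injected: whole-column shuffles (a non-identity
#' permutation of the column's times, destroying linearity) and a
#' compound offset (+magnitude minutes on a fraction of columns,
#' emulating a structurally dissimilar analyte).
#'
#' Defaults emulate the scale of the bundled Paridis panel: 4 saponins,
#' 30 columns, slopes ~ N(1, 0.07), intercepts ~ N(0, 1) min, noise sd
#' 0.05 min.
#'
#' @slot nColumns integer(1).
#' @slot stRTrue named numeric, true consensus retention times (minutes).
#' @slot slopeMean,slopeSd,interceptMean,interceptSd,noiseSd numeric(1).
#' @slot nShuffled integer(1), number of shuffled outlier columns.
#' @slot offsetCompound character(1), compound given the offset
#'   (\code{NA} for none).
#' @slot offsetMagnitude numeric(1), minutes.
#' @slot offsetFraction numeric(1), fraction of columns affected.
#' @slot seed integer(1), mandatory.
#' @exportClass PanelSpec
.PanelSpec <- setClass("PanelSpec",
    slots = c(nColumns = "integer", stRTrue = "numeric",
              slopeMean = "numeric", slopeSd = "numeric",
              interceptMean = "numeric", interceptSd = "numeric",
              noiseSd = "numeric", nShuffled = "integer",
              offsetCompound = "character", offsetMagnitude = "numeric",
              offsetFraction = "numeric", seed = "integer"))

setValidity("PanelSpec", function(object) {
    msg <- character(0)
    if (object@nColumns < 1L)
        msg <- c(msg, "nColumns must be >= 1")
    if (length(object@stRTrue) < 2L || is.null(names(object@stRTrue)))
        msg <- c(msg, "stRTrue must be a named vector of >= 2 compounds")
    if (any(c(object@slopeSd, object@interceptSd, object@noiseSd) < 0))
        msg <- c(msg, "standard deviations must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a seed is mandatory")
    if (object@offsetFraction < 0 || object@offsetFraction > 1)
        msg <- c(msg, "offsetFraction must be in [0, 1]")
    if (object@nShuffled < 0L || object@nShuffled > object@nColumns)
        msg <- c(msg, "nShuffled must be between 0 and nColumns")
    if (length(msg)) msg else TRUE
})
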