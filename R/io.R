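#' Read a peak list from CSV
#'
#' Expects a header with a \code{retention_time_min} column (one
#' observed peak per row) and an optional \code{label} column.
#'
#' @param path path to a CSV file.
#' @return a \linkS4class{PeakList}.
#' @export
readPeakList <- function(path) {
    d <- read.csv(path, check.names = FALSE)
    if (!"retention_time_min" %in% colnames(d))
        stop("peak list CSV needs a 'retention_time_min' column")
    peakList(as.numeric(d$retention_time_min),
             labels = if ("label" %in% colnames(d))
                 as.character(d$label) else NULL)
}

#' Write / read a StandardRetention
#'
#' The values go to a two-column CSV (\code{compound},
#' \code{st_r_min}); the set of columns behind them goes to a JSON
#' sidecar \code{<path>.json} with field \code{columns_used}.
#'
#' @param strt a \linkS4class{StandardRetention}.
#' @param path CSV output path.
#' @return \code{path}, invisibly (for the writer); a
#'   \linkS4class{StandardRetention} (for the reader).
#' @export
writeStandardRetention <- function(strt, path) {
    write.csv(data.frame(compound = compounds(strt),
                         st_r_min = unname(stR(strt))),
              path, row.names = FALSE, quote = TRUE)
    jsonlite::write_json(list(columns_used = columnsUsed(strt)),
                         paste0(path, ".json"), auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writeStandardRetention
#' @export
readStandardRetention <- function(path) {
    d <- read.csv(path, check.names = FALSE)
    side <- paste0(path, ".json")
    cols <- if (file.exists(side))
        unlist(jsonlite::fromJSON(side)$columns_used)
    else "unknown"
    standardRetention(stats::setNames(as.numeric(d$st_r_min), d$compound),
                      cols)
}

# ---- report serialization ------------------------------------------------

.reportList <- function(object) {
    if (is(object, "MatchResult")) {
        lineInfo <- function(l) if (is.null(l)) NULL else
            list(slope = l@slope, intercept = l@intercept,
                 r = if (is.na(l@r)) NULL else l@r, method = l@method)
        list(type = "MatchResult", stage = object@stage,
             success = object@success,
             two_point_line = lineInfo(object@twoPointLine),
             multi_point_line = lineInfo(object@multiPointLine),
             config = list(t_r_window = object@config@tRWindow,
                           t_r_limit = object@config@tRLimit,
                           series_gap = object@config@seriesGap),
             results = object@results)
    } else if (is(object, "MethodReport")) {
        list(type = "MethodReport", method = object@method,
             max_dtr = object@maxDeltaTR, mean_dtr = object@meanDeltaTR,
             positive_columns = object@positiveColumns,
             t_r_limit = object@tRLimit, notes = object@notes,
             delta_table = as.data.frame(object@deltaTable))
    } else if (is(object, "ExclusionReport")) {
        list(type = "ExclusionReport",
             thresholds = object@thresholds,
             excluded_columns = object@excludedColumns,
             excluded_compounds = object@excludedCompounds,
             retained_columns = object@retainedColumns,
             retained_compounds = object@retainedCompounds,
             final_st_r = as.list(stR(object@finalStR)))
    } else if (is(object, "SubsampleSummary")) {
        list(type = "SubsampleSummary", seed = object@seed,
             summary = object@summary)
    } else if (is(object, "StandardRetention")) {
        list(type = "StandardRetention", st_r = as.list(stR(object)),
             columns_used = columnsUsed(object),
             n = nColumnsUsed(object))
    } else if (is.list(object)) {
        lapply(object, function(x) if (isS4(x)) .reportList(x) else x)
    } else stop("no report serialization for class ", class(object))
}

.writeJSONReport <- function(object, path) {
    # 17 significant digits: doubles survive the JSON round trip
    # bit-exactly
    jsonlite::write_json(.reportList(object), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, na = "null")
    invisible(path)
}

#' Read back a JSON report
#'
#' @param path a JSON file written by [writeReport()].
#' @return a list mirroring the JSON structure.
#' @export
readReport <- function(path) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

.formatLine <- function(l, tag) {
    sprintf("%s: tR = %.10g * StR %+.10g%s", tag, l@slope, l@intercept,
            if (is.na(l@r)) "" else sprintf(" (r = %.10g)", l@r))
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "MatchResult",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        if (format == "csv") {
            write.csv(object@results, path, row.names = FALSE)
            return(invisible(path))
        }
        con <- file(path, "w")
        on.exit(close(con))
        r <- object@results
        lines <- c("Two-reference calibration report",
                   .formatLine(object@twoPointLine, "two-point equation"))
        if (!is.null(object@multiPointLine))
            lines <- c(lines, .formatLine(object@multiPointLine,
                                          "multi-point equation"))
        for (i in seq_len(nrow(r))) {
            lines <- c(lines, sprintf(
                "%s: tR_pre(2pt) %.3f min, tR_mea %s, dTR(2pt) %s, tR_pre(multi) %s, dTR(multi) %s",
                r$analyte[i], r$tRPreTwoPoint[i],
                ifelse(is.na(r$tRMea[i]), "unassigned",
                       sprintf("%.3f min", r$tRMea[i])),
                ifelse(is.na(r$deltaTRTwoPoint[i]), "-",
                       sprintf("%.3f min", r$deltaTRTwoPoint[i])),
                ifelse(is.na(r$tRPreMultiPoint[i]), "-",
                       sprintf("%.3f min", r$tRPreMultiPoint[i])),
                ifelse(is.na(r$deltaTRMultiPoint[i]), "-",
                       sprintf("%.3f min", r$deltaTRMultiPoint[i]))))
        }
        lines <- c(lines, sprintf("prediction: %s",
                                  if (isTRUE(object@success)) "success"
                                  else "failure"))
        writeLines(lines, con)
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", "MethodReport",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        write.csv(methodSummary(list(object)), path, row.names = FALSE)
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", "list",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        if (all(vapply(object, function(x)
                is(x, "MethodReport") || is.data.frame(x), logical(1)))) {
            write.csv(methodSummary(object), path, row.names = FALSE)
            return(invisible(path))
        }
        stop("csv/text output is only defined for method-report lists")
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", "ExclusionReport",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c(
            "Panel exclusion report",
            sprintf("thresholds: r >= %.3f, residual <= %.2f min, compound fraction %.2f",
                    object@thresholds$rMin, object@thresholds$residMax,
                    object@thresholds$compoundFraction),
            sprintf("retained: %d columns, %d compounds",
                    length(object@retainedColumns),
                    length(object@retainedCompounds)),
            if (nrow(object@excludedColumns)) paste0(
                "excluded column ", object@excludedColumns$column, ": ",
                object@excludedColumns$reason) else "no columns excluded",
            if (nrow(object@excludedCompounds)) paste0(
                "excluded compound ", object@excludedCompounds$compound,
                ": ", object@excludedCompounds$reason)
            else "no compounds excluded"), con)
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", "SubsampleSummary",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        write.csv(object@summary, path, row.names = FALSE)
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", "StandardRetention",
    function(object, path, format = c("json", "csv", "text"), ...) {
        format <- match.arg(format)
        if (format == "json") return(.writeJSONReport(object, path))
        writeStandardRetention(object, path)
    })
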