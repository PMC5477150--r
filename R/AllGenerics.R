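#' @name lctrs-generics
#' @title Accessor generics
#' @description Small accessor generics for the package's S4 classes.
#' @param object an object of the documented class.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname lctrs-generics
#' @export
setGeneric("compounds", function(object, ...) standardGeneric("compounds"))

#' @rdname lctrs-generics
#' @export
setGeneric("columnIds", function(object, ...) standardGeneric("columnIds"))

#' @rdname lctrs-generics
#' @export
setGeneric("retentionTimes",
    function(object, ...) standardGeneric("retentionTimes"))

#' @rdname lctrs-generics
#' @export
setGeneric("retentionSD",
    function(object, ...) standardGeneric("retentionSD"))

#' @rdname lctrs-generics
#' @export
setGeneric("stR", function(object, ...) standardGeneric("stR"))

#' @rdname lctrs-generics
#' @export
setGeneric("columnsUsed", function(object, ...) standardGeneric("columnsUsed"))

#' @rdname lctrs-generics
#' @export
setGeneric("nColumnsUsed",
    function(object, ...) standardGeneric("nColumnsUsed"))

#' @rdname lctrs-generics
#' @export
setGeneric("slope", function(object, ...) standardGeneric("slope"))

#' @rdname lctrs-generics
#' @export
setGeneric("intercept", function(object, ...) standardGeneric("intercept"))

#' @rdname lctrs-generics
#' @export
setGeneric("corrCoef", function(object, ...) standardGeneric("corrCoef"))

#' @rdname lctrs-generics
#' @export
setGeneric("tRCoverage", function(object, ...) standardGeneric("tRCoverage"))

#' @rdname lctrs-generics
#' @export
setGeneric("peaks", function(object, ...) standardGeneric("peaks"))

#' @rdname lctrs-generics
#' @export
setGeneric("predicted", function(object, ...) standardGeneric("predicted"))

#' @rdname lctrs-generics
#' @export
setGeneric("matchSuccess",
    function(object, ...) standardGeneric("matchSuccess"))

#' @rdname lctrs-generics
#' @export
setGeneric("deltaTRValues",
    function(object, ...) standardGeneric("deltaTRValues"))

#' Write a result object to disk
#'
#' Serializes a result object as round-trippable JSON, as CSV, or as a
#' human-readable text report.
#'
#' @param object the result to write (a \linkS4class{MatchResult},
#'   \linkS4class{MethodReport} (or list thereof),
#'   \linkS4class{ExclusionReport}, \linkS4class{SubsampleSummary} or
#'   \linkS4class{StandardRetention}).
#' @param path output file path.
#' @param format \code{"json"}, \code{"csv"} or \code{"text"}.
#' @param ... passed to methods.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeReport",
    function(object, path, format = c("json", "csv", "text"), ...)
        standardGeneric("writeReport"))
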