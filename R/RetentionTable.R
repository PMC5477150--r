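#' Construct a RetentionTable
#'
#' @param tR numeric matrix of measured retention times (minutes),
#'   compounds in rows, chromatographic columns in columns; dimnames
#'   mandatory.
#' @param sd optional matrix of per-cell standard deviations (minutes),
#'   same dimensions and dimnames as \code{tR}.
#' @return a \linkS4class{RetentionTable}.
#' @examples
#' tab <- RetentionTable(matrix(c(10, 20, 11, 22), 2,
#'     dimnames = list(c("A", "B"), c("c1", "c2"))))
#' retentionTimes(tab)
#' @export
RetentionTable <- function(tR, sd = NULL) {
    tR <- as.matrix(tR)
    storage.mode(tR) <- "double"
    al <- list(tR = tR)
    if (!is.null(sd)) {
        sd <- as.matrix(sd)
        storage.mode(sd) <- "double"
        if (!identical(dim(sd), dim(tR)))
            stop("sd matrix must have the same dimensions as tR")
        dimnames(sd) <- dimnames(tR)
        al$sd <- sd
    }
    .RetentionTable(SummarizedExperiment(assays = al))
}

#' @rdname lctrs-generics
#' @export
setMethod("compounds", "RetentionTable", function(object, ...)
    rownames(object))

#' @rdname lctrs-generics
#' @export
setMethod("columnIds", "RetentionTable", function(object, ...)
    colnames(object))

#' @rdname lctrs-generics
#' @export
setMethod("retentionTimes", "RetentionTable", function(object, ...)
    assay(object, "tR"))

#' @rdname lctrs-generics
#' @export
setMethod("retentionSD", "RetentionTable", function(object, ...) {
    if ("sd" %in% assayNames(object)) assay(object, "sd") else NULL
})

setMethod("show", "RetentionTable", function(object) {
    cat("RetentionTable:", nrow(object), "compounds x",
        ncol(object), "chromatographic columns\n")
    cat("  compounds:", paste(utils::head(rownames(object), 4),
                              collapse = ", "),
        if (nrow(object) > 4) "..." else "", "\n")
    cat("  columns  :", paste(utils::head(colnames(object), 6),
                              collapse = ", "),
        if (ncol(object) > 6) "..." else "", "\n")
    if ("sd" %in% assayNames(object))
        cat("  replicate SDs available\n")
})

#' Read a retention table from CSV
#'
#' Expects a header row; the first column holds compound identifiers and
#' every remaining column one chromatographic column (cells: retention
#' time in minutes).  Columns named \code{<id>_sd} are interpreted as
#' per-cell standard deviations for column \code{<id>}.  Empty cells
#' become \code{NA} (the column must then be excluded before St_R
#' computation); non-numeric or non-positive cells are rejected with the
#' offending compound and column named.
#'
#' @param path path to a CSV file.
#' @return a \linkS4class{RetentionTable}.
#' @seealso [writeRetentionTable()]
#' @export
readRetentionTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                    strip.white = TRUE)
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stop("retention table must have at least one compound row and one column")
    cmp <- raw[[1L]]
    if (anyDuplicated(cmp))
        stop("duplicate compound identifiers: ",
             paste(unique(cmp[duplicated(cmp)]), collapse = ", "))
    cols <- colnames(raw)[-1L]
    if (anyDuplicated(cols))
        stop("duplicate column identifiers: ",
             paste(unique(cols[duplicated(cols)]), collapse = ", "))
    isSD <- grepl("_sd$", cols)
    parse <- function(colName) {
        cell <- raw[[colName]]
        v <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(v) & nzchar(cell))
        if (length(bad))
            stop(sprintf("non-numeric cell for compound '%s', column '%s': '%s'",
                         cmp[bad[1L]], colName, cell[bad[1L]]))
        neg <- which(!is.na(v) & v <= 0)
        if (length(neg))
            stop(sprintf(
                "retention time must be positive: compound '%s', column '%s' (%s)",
                cmp[neg[1L]], colName, cell[neg[1L]]))
        v
    }
    tR <- vapply(cols[!isSD], parse, numeric(nrow(raw)))
    tR <- matrix(tR, nrow = nrow(raw),
                 dimnames = list(cmp, cols[!isSD]))
    sd <- NULL
    if (any(isSD)) {
        base <- sub("_sd$", "", cols[isSD])
        if (!all(base %in% cols[!isSD]))
            stop("_sd columns without a matching retention column: ",
                 paste(base[!base %in% cols[!isSD]], collapse = ", "))
        sd <- matrix(NA_real_, nrow(raw), sum(!isSD),
                     dimnames = dimnames(tR))
        for (b in base)
            sd[, b] <- suppressWarnings(as.numeric(raw[[paste0(b, "_sd")]]))
    }
    RetentionTable(tR, sd = sd)
}

#' Write a retention table to CSV
#'
#' Inverse of [readRetentionTable()]; per-cell standard deviations, when
#' present, are written as parallel \code{<id>_sd} columns.
#'
#' @param table a \linkS4class{RetentionTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRetentionTable <- function(table, path) {
    m <- retentionTimes(table)
    out <- data.frame(compound = rownames(m), check.names = FALSE)
    out[colnames(m)] <- as.data.frame(m, check.names = FALSE)
    s <- retentionSD(table)
    if (!is.null(s))
        out[paste0(colnames(m), "_sd")] <- as.data.frame(s,
                                                         check.names = FALSE)
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}
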