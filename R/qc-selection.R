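#' Fit one column's measured times against St_R
#'
#' Ordinary least-squares line of a column's measured retention times on
#' the consensus St_R profile, with per-compound absolute residuals and
#' the Pearson correlation of the points.  On well-behaved panels the
#' correlation is very close to 1; a clearly lower value flags a column
#' whose retention behaviour is not an affine image of the consensus.
#'
#' @param table a \linkS4class{RetentionTable}.
#' @param strt a \linkS4class{StandardRetention}.
#' @param column a column identifier of \code{table}.
#' @return a \linkS4class{ColumnFit}.
#' @export
fitColumnVsStR <- function(table, strt, column) {
    if (!column %in% columnIds(table))
        stop("unknown column: ", column)
    st <- stR(strt)
    cmp <- intersect(names(st), compounds(table))
    if (length(cmp) < 2L)
        stop("column fitting needs at least two compounds")
    y <- retentionTimes(table)[cmp, column]
    fit <- .ols(st[cmp], y)
    .ColumnFit(column = column,
               line = .CalibrationLine(slope = fit$slope,
                                       intercept = fit$intercept,
                                       r = fit$r,
                                       method = "least_squares"),
               residuals = stats::setNames(abs(fit$residuals), cmp))
}

#' @rdname lctrs-generics
#' @export
setMethod("corrCoef", "ColumnFit", function(object, ...) object@line@r)

setMethod("show", "ColumnFit", function(object) {
    cat(sprintf("ColumnFit '%s': ", object@column))
    show(object@line)
    cat("  max |residual|:", round(max(object@residuals), 3), "min\n")
})

#' Detect outlier columns and compounds
#'
#' Fits every complete column of the panel against the initial St_R and
#' applies the exclusion heuristics: a column is an outlier when its
#' correlation coefficient falls below \code{rMin} (default 0.99) or any
#' of its residuals exceeds \code{residMax} (default 1.5 min, the middle
#' of the 1-2 min rule of thumb); a compound is an outlier ("obviously
#' deviating from the regression line") when its residual exceeds
#' \code{residMax} on more than \code{compoundFraction} of the columns.
#' For the compound rule the signed residuals are first centered by the
#' compound's median residual across columns: a compound that misbehaves
#' on a subset of columns also contaminates the consensus St_R, shifting
#' all of its residuals towards zero, which would otherwise mask the
#' deviation; centering on the clean-majority median removes that bias.
#' The final St_R is then recomputed from the retained columns and
#' compounds in a single pass (initial St_R, one exclusion round, final
#' St_R); excluded columns and compounds do not enter it.
#'
#' @param table a \linkS4class{RetentionTable}.
#' @param rMin minimum acceptable Pearson correlation per column.
#' @param residMax maximum acceptable absolute residual (minutes).
#' @param compoundFraction fraction of columns on which a compound may
#'   exceed \code{residMax} before it is excluded.
#' @return an \linkS4class{ExclusionReport}.
#' @export
detectOutliers <- function(table, rMin = 0.99, residMax = 1.5,
                           compoundFraction = 0.25) {
    m <- retentionTimes(table)
    complete <- colnames(m)[colSums(is.na(m)) == 0L]
    if (length(complete) == 0L)
        stop("no complete columns in the panel")
    strt0 <- computeStR(table, complete)
    fits <- lapply(complete, function(cc) fitColumnVsStR(table, strt0, cc))
    names(fits) <- complete

    rs <- vapply(fits, corrCoef, numeric(1))
    maxRes <- vapply(fits, function(f) max(f@residuals), numeric(1))
    colBad <- (!is.na(rs) & rs < rMin) | maxRes > residMax
    colReason <- ifelse(!is.na(rs) & rs < rMin,
                        sprintf("r = %.4f < %.2f", rs, rMin),
                        sprintf("max residual %.3f min > %.2f min",
                                maxRes, residMax))

    # signed residuals (compounds x columns), median-centered per
    # compound so that St_R contamination by an outlying subset of
    # columns cannot mask the compound's own deviation
    resMat <- vapply(complete, function(cc) {
        fit <- .ols(stR(strt0), m[, cc])
        fit$residuals
    }, numeric(nrow(m)))
    rownames(resMat) <- rownames(m)
    centered <- resMat - apply(resMat, 1L, stats::median)
    frac <- rowMeans(abs(centered) > residMax)
    cmpBad <- frac > compoundFraction
    cmpReason <- sprintf(
        "residual > %.2f min on %.0f%% of columns (threshold %.0f%%)",
        residMax, 100 * frac, 100 * compoundFraction)

    keepCols <- complete[!colBad]
    keepCmp <- rownames(m)[!cmpBad]
    if (length(keepCols) == 0L)
        stop("all columns excluded as outliers; check the panel or relax ",
             "the thresholds")
    if (length(keepCmp) < 2L)
        stop("fewer than two compounds retained; check the panel")

    finalFull <- computeStR(table, keepCols)
    final <- standardRetention(stR(finalFull)[keepCmp], keepCols)
    .ExclusionReport(
        excludedColumns = data.frame(column = complete[colBad],
                                     reason = colReason[colBad],
                                     stringsAsFactors = FALSE),
        excludedCompounds = data.frame(compound = rownames(m)[cmpBad],
                                       reason = cmpReason[cmpBad],
                                       stringsAsFactors = FALSE),
        retainedColumns = keepCols,
        retainedCompounds = keepCmp,
        finalStR = final,
        thresholds = list(rMin = rMin, residMax = residMax,
                          compoundFraction = compoundFraction))
}

setMethod("show", "ExclusionReport", function(object) {
    cat("ExclusionReport\n")
    cat("  retained:", length(object@retainedColumns), "columns,",
        length(object@retainedCompounds), "compounds\n")
    if (nrow(object@excludedColumns)) {
        cat("  excluded columns:\n")
        print(object@excludedColumns, row.names = FALSE)
    } else cat("  no columns excluded\n")
    if (nrow(object@excludedCompounds)) {
        cat("  excluded compounds:\n")
        print(object@excludedCompounds, row.names = FALSE)
    } else cat("  no compounds excluded\n")
})

#' Select the two reference compounds
#'
#' Three-step procedure: (1) keep the candidate pairs whose coverage of
#' t_R is at least \code{coverageMin} (default 0.8: references near both
#' ends of the retention span); (2) drop pairs containing excluded or
#' high-deviation compounds; (3) score every surviving pair by the mean
#' two-point deviation over all panel columns and all non-reference
#' compounds, and return the pair with the smallest mean deviation
#' together with the full ranking.
#'
#' @param table a \linkS4class{RetentionTable}.
#' @param strt a \linkS4class{StandardRetention}; computed from all
#'   complete columns when \code{NULL}.
#' @param candidates compound identifiers eligible as references;
#'   defaults to all compounds of \code{strt}.
#' @param coverageMin minimum coverage of t_R (fraction).
#' @param excludeCompounds compounds that may not serve as references
#'   (e.g. from [detectOutliers()]).
#' @return a list with elements \code{pair} (a
#'   \linkS4class{ReferencePair}) and \code{ranking} (a data.frame with
#'   columns \code{first}, \code{second}, \code{coverage},
#'   \code{meanDeltaTR}, sorted by score).
#' @export
selectReferencePair <- function(table, strt = NULL, candidates = NULL,
                                coverageMin = 0.8,
                                excludeCompounds = character(0)) {
    m <- retentionTimes(table)
    if (is.null(strt)) {
        complete <- colnames(m)[colSums(is.na(m)) == 0L]
        strt <- computeStR(table, complete)
    }
    st <- stR(strt)
    if (is.null(candidates)) candidates <- names(st)
    candidates <- setdiff(candidates, excludeCompounds)
    if (length(candidates) < 2L)
        stop("need at least two candidate compounds after exclusion")
    cols <- intersect(columnsUsed(strt), colnames(m))
    pairsIdx <- utils::combn(candidates, 2L, simplify = FALSE)
    score <- function(p) {
        p <- p[order(st[p])]
        cov <- .coverageValue(st[[p[1L]]], st[[p[2L]]], st)
        others <- setdiff(rownames(m), p)
        d <- vapply(cols, function(cc) {
            a <- (m[p[2L], cc] - m[p[1L], cc]) / (st[[p[2L]]] - st[[p[1L]]])
            b <- m[p[1L], cc] - a * st[[p[1L]]]
            mean(abs(m[others, cc] - (a * st[others] + b)))
        }, numeric(1))
        c(coverage = cov, meanDeltaTR = mean(d))
    }
    sc <- t(vapply(pairsIdx, score, numeric(2)))
    rk <- data.frame(
        first = vapply(pairsIdx, function(p) p[order(st[p])][1L], ""),
        second = vapply(pairsIdx, function(p) p[order(st[p])][2L], ""),
        coverage = sc[, "coverage"],
        meanDeltaTR = sc[, "meanDeltaTR"],
        stringsAsFactors = FALSE)
    rk <- rk[order(rk$meanDeltaTR), , drop = FALSE]
    rownames(rk) <- NULL
    ok <- rk$coverage >= coverageMin
    if (!any(ok))
        stop(sprintf(
            "no candidate pair reaches coverage %.2f (best: %.2f); ",
            coverageMin, max(rk$coverage)),
            "consider lowering coverageMin")
    best <- rk[ok, ][1L, ]
    list(pair = referencePair(strt, best$first, best$second),
         ranking = rk)
}

#' Column-subsampling study of the St_R panel size
#'
#' How many columns does a reliable St_R need?  For each subset size k,
#' random non-replicate subsets of the panel's columns are drawn, St_R is
#' computed on the subset, and every column of the full panel is refitted
#' by a multiple-point regression against that subset St_R.  The recorded
#' statistic per draw is the mean absolute deviation between measured and
#' fitted times over all compounds and columns; the summary reports its
#' mean and standard deviation over the draws of each k.  Draw counts are
#' capped at choose(N, k) so subsets are never repeated, and results are
#' reproducible under the given seed.
#'
#' @param table a \linkS4class{RetentionTable} (complete panel).
#' @param kValues integer vector of subset sizes.
#' @param nDraws integer vector of draw counts, recycled along
#'   \code{kValues}.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a \linkS4class{SubsampleSummary}.
#' @export
subsampleStudy <- function(table, kValues = c(1, 5, 10, 15, 20, 25, 30),
                           nDraws = c(30, 100, 100, 100, 100, 100, 1),
                           seed) {
    if (missing(seed))
        stop("a seed is required for the subsampling study")
    m <- retentionTimes(table)
    if (anyNA(m))
        stop("the subsampling study needs a complete panel")
    N <- ncol(m)
    if (any(kValues > N))
        stop("subset size k cannot exceed the number of columns (", N, ")")
    if (any(kValues < 1L))
        stop("subset size k must be >= 1")
    nDraws <- rep_len(nDraws, length(kValues))
    rows <- .withSeed(seed, lapply(seq_along(kValues), function(ki) {
        k <- kValues[ki]
        n <- min(nDraws[ki], choose(N, k))
        seen <- new.env(parent = emptyenv())
        out <- numeric(0)
        tries <- 0L
        while (length(out) < n) {
            tries <- tries + 1L
            if (tries > 1000L * n)
                stop("could not draw enough distinct subsets")
            idx <- sort(sample.int(N, k))
            key <- paste(idx, collapse = ",")
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            sst <- rowMeans(m[, idx, drop = FALSE])
            xc <- sst - mean(sst)
            slopes <- as.numeric(crossprod(xc, m)) / sum(xc^2)
            bs <- colMeans(m) - slopes * mean(sst)
            fitted <- outer(sst, slopes) +
                matrix(bs, nrow(m), N, byrow = TRUE)
            out <- c(out, mean(abs(m - fitted)))
        }
        data.frame(k = k, nDraws = n, meanDeltaTR = mean(out),
                   sdDeltaTR = if (n > 1L) sd(out) else 0)
    }))
    .SubsampleSummary(summary = do.call(rbind, rows),
                      seed = as.integer(seed))
}

setMethod("show", "SubsampleSummary", function(object) {
    cat("SubsampleSummary (seed", object@seed, ")\n")
    print(transform(object@summary,
                    meanDeltaTR = round(meanDeltaTR, 4),
                    sdDeltaTR = round(sdDeltaTR, 4)), row.names = FALSE)
})
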