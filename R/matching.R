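#' Matching configuration
#'
#' @param tRWindow half-width t_R_W of the peak search window (minutes);
#'   recommended range 0.8-2.0.
#' @param tRLimit acceptance limit t_R_L applied after multiple-point
#'   validation (minutes); recommended range 0.5-1.5; must not exceed
#'   \code{tRWindow}.
#' @param seriesGap predictions closer than this (minutes) that share a
#'   candidate peak are treated as a peak series and matched
#'   sequentially.
#' @param overrides optional data.frame with columns \code{compound},
#'   \code{tRWindow}, \code{tRLimit} giving per-compound values
#'   (\code{NA} entries fall back to the global values).
#' @return a \linkS4class{MatchConfig}.
#' @export
matchConfig <- function(tRWindow = 1.2, tRLimit = 0.5, seriesGap = 2.0,
                        overrides = NULL) {
    if (is.null(overrides))
        overrides <- data.frame(compound = character(0),
                                tRWindow = numeric(0),
                                tRLimit = numeric(0))
    .MatchConfig(tRWindow = tRWindow, tRLimit = tRLimit,
                 seriesGap = seriesGap, overrides = overrides)
}

# Per-analyte window/limit after applying overrides.
.effectiveLimits <- function(cfg, analytes) {
    w <- rep(cfg@tRWindow, length(analytes))
    l <- rep(cfg@tRLimit, length(analytes))
    ov <- cfg@overrides
    if (nrow(ov)) {
        i <- match(analytes, ov$compound)
        hit <- !is.na(i)
        w[hit] <- ifelse(is.na(ov$tRWindow[i[hit]]), w[hit],
                         ov$tRWindow[i[hit]])
        l[hit] <- ifelse(is.na(ov$tRLimit[i[hit]]), l[hit],
                         ov$tRLimit[i[hit]])
    }
    list(window = w, limit = l)
}

#' Observed peak list
#'
#' @param times numeric, observed peak retention times (minutes); sorted
#'   internally, duplicates are rejected.
#' @param labels optional character labels, parallel to \code{times}.
#' @return a \linkS4class{PeakList}.
#' @export
peakList <- function(times, labels = NULL) {
    o <- order(times)
    .PeakList(peaks = times[o],
              labels = if (is.null(labels)) character(0) else labels[o])
}

#' @rdname lctrs-generics
#' @export
setMethod("peaks", "PeakList", function(object, ...) object@peaks)

setMethod("show", "PeakList", function(object) {
    cat("PeakList:", length(object@peaks), "peaks\n")
    print(round(object@peaks, 3))
})

#' Sequential (order-preserving) matching of a peak series
#'
#' When two or more predicted times are close and their search windows
#' share a candidate peak, least-deviation matching can assign two
#' predictions to the same observed peak and leave its true partner
#' unmatched.  The sequential rule resolves the series instead: the
#' predictions, in order of predicted time, are matched one-to-one to
#' the candidate peaks in order of observed time (the earlier prediction
#' takes the earlier peak), even when this increases an individual
#' deviation.  Each prediction only accepts a peak inside its own
#' window; when the series has fewer candidate peaks than members, the
#' trailing members stay unassigned.
#'
#' @param seriesPreds numeric, predicted times of the series members
#'   (sorted ascending).
#' @param seriesPeaks numeric, candidate observed peak times (sorted
#'   ascending); typically the union of the members' window contents.
#' @param windows numeric, per-member window half-widths (recycled).
#' @return integer vector: for each prediction the index into
#'   \code{seriesPeaks} of the assigned peak, or \code{NA}.
#' @export
sequentialMatch <- function(seriesPreds, seriesPeaks,
                            windows = Inf) {
    nP <- length(seriesPreds)
    windows <- rep_len(windows, nP)
    if (is.unsorted(seriesPreds) || is.unsorted(seriesPeaks))
        stop("series predictions and candidate peaks must be sorted")
    assign <- rep(NA_integer_, nP)
    nextIdx <- 1L
    for (i in seq_len(nP)) {
        j <- nextIdx
        while (j <= length(seriesPeaks) &&
               seriesPeaks[j] < seriesPreds[i] - windows[i])
            j <- j + 1L
        if (j <= length(seriesPeaks) &&
            seriesPeaks[j] <= seriesPreds[i] + windows[i]) {
            assign[i] <- j
            nextIdx <- j + 1L
        } else {
            nextIdx <- j
        }
    }
    assign
}

#' Match predicted analytes to observed peaks
#'
#' Each analyte is assigned the observed peak with the smallest
#' deviation among the peaks inside its window [t_R_pre - t_R_W,
#' t_R_pre + t_R_W] (ties go to the earlier peak).  Before finalizing,
#' analytes whose predictions are closer than the series gap and whose
#' windows share at least one candidate peak are treated as a peak
#' series and resolved with the order-preserving [sequentialMatch()]
#' rule.  Outside a series an observed peak may be claimed by only one
#' analyte; a conflict is resolved in favour of the smaller deviation
#' and the loser stays unassigned.  Analytes whose windows contain no
#' peak are reported unassigned (not an error).
#'
#' @param preds a \linkS4class{PredictionSet} or a named numeric vector
#'   of predicted times.
#' @param peaks a \linkS4class{PeakList} or numeric vector of observed
#'   peak times.
#' @param cfg a \linkS4class{MatchConfig}.
#' @return a \linkS4class{MatchResult} with stage \code{"two_point"};
#'   \code{success} is \code{TRUE} when every analyte was assigned.
#' @export
matchPeaks <- function(preds, peaks, cfg = matchConfig()) {
    if (is(preds, "PredictionSet")) {
        pv <- predicted(preds)
        line <- preds@line
        stvals <- (pv - line@intercept) / line@slope
    } else {
        pv <- preds
        line <- calibrationLine(1, 0, method = "least_squares")
        stvals <- rep(NA_real_, length(pv))
    }
    if (is(peaks, "PeakList")) peaks <- peaks(peaks)
    peaks <- sort(peaks)
    analytes <- names(pv)
    nA <- length(pv)
    lims <- .effectiveLimits(cfg, analytes)

    ord <- order(pv)
    cand <- lapply(seq_len(nA), function(i)
        which(peaks >= pv[i] - lims$window[i] &
              peaks <= pv[i] + lims$window[i]))

    # group sorted analytes into series: consecutive predictions closer
    # than the gap whose windows share a candidate peak
    grp <- integer(nA)
    g <- 0L
    for (k in seq_len(nA)) {
        i <- ord[k]
        if (k == 1L) { g <- 1L; grp[i] <- g; next }
        prev <- ord[k - 1L]
        if (pv[i] - pv[prev] < cfg@seriesGap &&
            length(intersect(cand[[i]], cand[[prev]])))
            grp[i] <- g
        else { g <- g + 1L; grp[i] <- g }
    }

    assigned <- rep(NA_integer_, nA)
    used <- rep(FALSE, length(peaks))
    gsize <- table(grp)
    seriesIds <- as.integer(names(gsize)[gsize >= 2L])
    for (gg in seriesIds) {
        members <- ord[grp[ord] == gg]
        candAll <- sort(unique(unlist(cand[members])))
        candAll <- candAll[!used[candAll]]
        sel <- sequentialMatch(pv[members], peaks[candAll],
                               windows = lims$window[members])
        assigned[members] <- candAll[sel]
        used[assigned[members][!is.na(assigned[members])]] <- TRUE
    }
    # singletons: least-deviation assignment among unconsumed peaks,
    # global greedy by deviation so conflicts go to the smaller delta
    singles <- ord[!grp[ord] %in% seriesIds]
    if (length(singles)) {
        entries <- do.call(rbind, lapply(singles, function(i) {
            js <- cand[[i]][!used[cand[[i]]]]
            if (!length(js)) return(NULL)
            data.frame(i = i, j = js, d = abs(peaks[js] - pv[i]))
        }))
        if (!is.null(entries) && nrow(entries)) {
            entries <- entries[order(entries$d, peaks[entries$j]), ,
                               drop = FALSE]
            claimed <- rep(FALSE, nA)
            for (k in seq_len(nrow(entries))) {
                i <- entries$i[k]; j <- entries$j[k]
                if (claimed[i]) next
                if (used[j]) {
                    # this analyte's best available peak is taken by a
                    # smaller-deviation rival: it stays unassigned
                    claimed[i] <- TRUE
                    next
                }
                assigned[i] <- j
                used[j] <- TRUE
                claimed[i] <- TRUE
            }
        }
    }

    tMea <- ifelse(is.na(assigned), NA_real_, peaks[assigned])
    dlt <- ifelse(is.na(assigned), NA_real_, abs(tMea - pv))
    res <- data.frame(analyte = analytes, stR = unname(stvals),
                      tRPreTwoPoint = unname(pv), tRMea = unname(tMea),
                      deltaTRTwoPoint = unname(dlt),
                      withinWindow = !is.na(assigned),
                      tRPreMultiPoint = rep(NA_real_, nA),
                      deltaTRMultiPoint = rep(NA_real_, nA),
                      withinLimit = rep(NA, nA),
                      stringsAsFactors = FALSE)
    .MatchResult(results = res, twoPointLine = line, multiPointLine = NULL,
                 stage = "two_point", success = all(!is.na(assigned)),
                 config = cfg)
}
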