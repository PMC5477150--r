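#' Bundled Paridis reference panel
#'
#' Measured retention times (and replicate standard deviations) of the
#' four Chonglou saponins of Paridis Rhizome on a panel of 30 C18
#' columns from 13 manufacturers, all run under one gradient program.
#' This is the package's worked reference dataset: its column means give
#' the consensus St_R profile, and columns \code{col1}-\code{col30}
#' serve as target columns in the examples and tests.
#'
#' @return a \linkS4class{RetentionTable}, 4 compounds x 30 columns.
#' @examples
#' tab <- paridisRetention()
#' round(stR(computeStR(tab)), 3)
#' @export
paridisRetention <- function() {
    tr <- system.file("extdata", "paridis_retention.csv",
                      package = "lctrs", mustWork = TRUE)
    sdp <- system.file("extdata", "paridis_retention_sd.csv",
                       package = "lctrs", mustWork = TRUE)
    tab <- readRetentionTable(tr)
    sdt <- read.csv(sdp, check.names = FALSE)
    sdm <- as.matrix(sdt[, -1L])
    rownames(sdm) <- sdt[[1L]]
    RetentionTable(retentionTimes(tab), sd = sdm)
}

#' Bundled Paridis relative-retention values
#'
#' The published RR values of the four saponins with Chonglou saponin II
#' as the reference compound.  They are taken as supplied (not
#' recomputed from the retention panel) and carry no dead time; supply
#' \code{t0} to enable the adjusted variant.
#'
#' @param t0 optional dead time in minutes to attach to the model.
#' @return an \linkS4class{RRModel}.
#' @export
paridisRR <- function(t0 = NA_real_) {
    p <- system.file("extdata", "paridis_rr.csv", package = "lctrs",
                     mustWork = TRUE)
    d <- read.csv(p, check.names = FALSE)
    rrModel(stats::setNames(d$rr, d$compound),
            reference = d$compound[d$reference][1L], t0 = t0)
}

#' Bundled Paridis St_R values as published
#'
#' The published per-compound St_R table.  Note that the published value
#' for Chonglou saponin VI (22.156 min) differs from the mean of the
#' published retention matrix (22.110 min); the package treats the
#' matrix, via [computeStR()] on [paridisRetention()], as the source of
#' truth (the worked two-point example is consistent with 22.110), and
#' keeps this table only as the published reference.
#'
#' @return a \linkS4class{StandardRetention} (columns used: the full
#'   30-column panel).
#' @export
paridisStRPrinted <- function() {
    p <- system.file("extdata", "paridis_str_printed.csv",
                     package = "lctrs", mustWork = TRUE)
    d <- read.csv(p, check.names = FALSE)
    standardRetention(stats::setNames(d$st_r_min, d$compound),
                      sprintf("col%d", 1:30))
}

#' The published Paridis reference pair
#'
#' Chonglou saponins VII and I: the first- and last-eluting saponins,
#' coverage of t_R equal to 1.
#'
#' @param strt the \linkS4class{StandardRetention} to attach the pair
#'   to; defaults to the profile computed from [paridisRetention()].
#' @return a \linkS4class{ReferencePair}.
#' @export
paridisReferencePair <- function(strt = computeStR(paridisRetention())) {
    referencePair(strt, "Chonglou saponin VII", "Chonglou saponin I")
}
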