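#' Specify a synthetic retention panel
#'
#' See \linkS4class{PanelSpec} for the generative model.  Defaults state
#' a Paridis-scale world: four saponins with the bundled consensus
#' retention times, 30 columns, per-column slopes ~ N(1, 0.07),
#' intercepts ~ N(0, 1) min and measurement noise of 0.05 min; no
#' injected outliers.
#'
#' @param nColumns number of columns in the panel.
#' @param stRTrue named numeric of true consensus retention times
#'   (minutes).
#' @param slopeMean,slopeSd,interceptMean,interceptSd distribution of
#'   the per-column affine maps.
#' @param noiseSd i.i.d. Gaussian measurement noise (minutes).
#' @param nShuffled number of columns whose times are scrambled by a
#'   non-identity permutation (outlier columns).
#' @param offsetCompound compound given a retention offset on a fraction
#'   of columns (outlier compound); \code{NA} for none.
#' @param offsetMagnitude offset in minutes.
#' @param offsetFraction fraction of columns carrying the offset.
#' @param seed integer seed; mandatory.
#' @return a \linkS4class{PanelSpec}.
#' @export
panelSpec <- function(nColumns = 30,
                      stRTrue = c("Chonglou saponin VII" = 19.803,
                                  "Chonglou saponin VI" = 22.110,
                                  "Chonglou saponin II" = 30.319,
                                  "Chonglou saponin I" = 33.035),
                      slopeMean = 1, slopeSd = 0.07,
                      interceptMean = 0, interceptSd = 1,
                      noiseSd = 0.05,
                      nShuffled = 0, offsetCompound = NA_character_,
                      offsetMagnitude = 3, offsetFraction = 0.4,
                      seed) {
    if (missing(seed)) stop("a seed is mandatory for a panel spec")
    .PanelSpec(nColumns = as.integer(nColumns), stRTrue = stRTrue,
               slopeMean = slopeMean, slopeSd = slopeSd,
               interceptMean = interceptMean, interceptSd = interceptSd,
               noiseSd = noiseSd, nShuffled = as.integer(nShuffled),
               offsetCompound = offsetCompound,
               offsetMagnitude = offsetMagnitude,
               offsetFraction = offsetFraction, seed = as.integer(seed))
}

#' Generate a synthetic retention panel
#'
#' Draws per-column slopes and intercepts, builds each column as an
#' affine image of the true St_R profile plus Gaussian noise, then
#' injects the requested outliers (shuffled columns first, then the
#' compound offset on a random draw of the remaining columns).  The
#' ground truth is returned alongside the table for parameter-recovery
#' tests.  Identical specs (including the seed) give identical panels.
#'
#' @param spec a \linkS4class{PanelSpec}.
#' @return a list with elements \code{table} (a
#'   \linkS4class{RetentionTable}) and \code{truth} (list: \code{stRTrue},
#'   \code{slopes}, \code{intercepts}, \code{shuffledColumns},
#'   \code{offsetColumns}, \code{offsetCompound}).
#' @examples
#' sim <- generatePanel(panelSpec(seed = 1))
#' sim$table
#' @export
generatePanel <- function(spec) {
    stopifnot(is(spec, "PanelSpec"))
    validObject(spec)
    .withSeed(spec@seed, {
        n <- spec@nColumns
        k <- length(spec@stRTrue)
        a <- rnorm(n, spec@slopeMean, spec@slopeSd)
        b <- rnorm(n, spec@interceptMean, spec@interceptSd)
        eps <- matrix(rnorm(k * n, 0, spec@noiseSd), k, n)
        m <- outer(spec@stRTrue, a) + matrix(b, k, n, byrow = TRUE) + eps
        colnames(m) <- sprintf("simcol%d", seq_len(n))
        rownames(m) <- names(spec@stRTrue)
        names(a) <- names(b) <- colnames(m)

        shuffled <- integer(0)
        if (spec@nShuffled > 0L) {
            shuffled <- sample.int(n, spec@nShuffled)
            for (j in shuffled) {
                repeat {
                    p <- sample.int(k)
                    if (any(p != seq_len(k))) break
                }
                m[, j] <- m[p, j]
            }
        }
        offCols <- integer(0)
        if (!is.na(spec@offsetCompound)) {
            if (!spec@offsetCompound %in% rownames(m))
                stop("offsetCompound not in stRTrue: ", spec@offsetCompound)
            pool <- setdiff(seq_len(n), shuffled)
            nOff <- round(spec@offsetFraction * n)
            if (nOff > length(pool))
                stop("offsetFraction too large given the shuffled columns")
            offCols <- sort(sample(pool, nOff))
            m[spec@offsetCompound, offCols] <-
                m[spec@offsetCompound, offCols] + spec@offsetMagnitude
        }
        if (any(m <= 0))
            stop("generated panel contains non-positive retention times; ",
                 "reduce the noise/intercept scale or increase stRTrue")
        list(table = RetentionTable(m),
             truth = list(stRTrue = spec@stRTrue, slopes = a,
                          intercepts = b,
                          shuffledColumns = colnames(m)[shuffled],
                          offsetColumns = colnames(m)[offCols],
                          offsetCompound = spec@offsetCompound))
    })
}
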