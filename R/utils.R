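# Closed-form ordinary least squares for y = slope * x + intercept with
# vertical residuals.  Returns Pearson r only for n >= 3 (a two-point fit
# interpolates, so r carries no information) and standard errors only for
# n >= 3 (residual-based) unless a known noise sd is supplied.
.ols <- function(x, y, sigma = NA_real_) {
    n <- length(x)
    if (n != length(y))
        stop("x and y must have equal length")
    if (n < 2L)
        stop("at least two points are required to fit a line")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("non-finite values in regression input")
    xb <- mean(x)
    yb <- mean(y)
    sxx <- sum((x - xb)^2)
    if (sxx <= 0)
        stop("degenerate fit: all abscissae are identical")
    sxy <- sum((x - xb) * (y - yb))
    slope <- sxy / sxx
    intercept <- yb - slope * xb
    fitted <- slope * x + intercept
    res <- y - fitted
    syy <- sum((y - yb)^2)
    r <- if (n >= 3L && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
    if (is.na(sigma)) {
        s2 <- if (n > 2L) sum(res^2) / (n - 2L) else NA_real_
    } else {
        s2 <- sigma^2
    }
    list(slope = slope, intercept = intercept, r = r,
         fitted = fitted, residuals = res,
         seSlope = sqrt(s2 / sxx),
         seIntercept = sqrt(s2 * (1 / n + xb^2 / sxx)),
         n = n)
}

# Evaluate expr with the global RNG temporarily seeded; the caller's RNG
# state is restored afterwards, so no global state leaks out of a run.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.assertScalarNumber <- function(x, what) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(what, " must be a single finite number")
    invisible(x)
}

.stageLog <- function(stage, ...) {
    message(sprintf("[lctrs] %s: %s", stage, paste0(...)))
}
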