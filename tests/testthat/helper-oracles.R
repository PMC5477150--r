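# Independent oracles used by the property tests.

# Brute-force least squares: grid search over (slope, intercept) with
# iterative refinement of the summed squared vertical residuals.  Stays
# independent of any closed-form fit in the package.
bruteForceLS <- function(x, y, slopeBox = c(-5, 5),
                         interceptBox = c(-60, 60), iters = 35L) {
    sse <- function(a, b) sum((y - (a * x + b))^2)
    for (it in seq_len(iters)) {
        as <- seq(slopeBox[1], slopeBox[2], length.out = 21L)
        bs <- seq(interceptBox[1], interceptBox[2], length.out = 21L)
        grid <- outer(as, bs, Vectorize(sse))
        idx <- arrayInd(which.min(grid), dim(grid))
        a0 <- as[idx[1]]; b0 <- bs[idx[2]]
        da <- diff(slopeBox) / 8; db <- diff(interceptBox) / 8
        slopeBox <- c(a0 - da, a0 + da)
        interceptBox <- c(b0 - db, b0 + db)
    }
    c(slope = a0, intercept = b0)
}

# All injective partial assignments of n predictions to m peaks
# (NA = unassigned), as a list of integer vectors of length n.
enumerateAssignments <- function(n, m) {
    grow <- function(prefix) {
        if (length(prefix) == n) return(list(prefix))
        free <- setdiff(seq_len(m), prefix[!is.na(prefix)])
        out <- list()
        for (j in c(NA_integer_, free))
            out <- c(out, grow(c(prefix, j)))
        out
    }
    grow(integer(0))
}

# feasibility / order-preservation predicates for an assignment
assignmentFeasible <- function(assign, preds, pks, windows) {
    ok <- TRUE
    for (i in seq_along(assign)) {
        if (is.na(assign[i])) next
        ok <- ok && abs(pks[assign[i]] - preds[i]) <= windows[i]
    }
    ok
}

assignmentOrdered <- function(assign) {
    j <- assign[!is.na(assign)]
    length(j) < 2L || all(diff(j) > 0)
}

paridisCompounds <- c("Chonglou saponin VII", "Chonglou saponin VI",
                      "Chonglou saponin II", "Chonglou saponin I")
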