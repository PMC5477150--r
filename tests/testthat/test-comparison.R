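test_that("RR prediction reproduces the worst Paridis case", {
    tab <- paridisRetention()
    rrm <- paridisRR()
    m <- retentionTimes(tab)
    pred <- rrPredict(rrm, m["Chonglou saponin II", "col2"],
                      "Chonglou saponin VI")
    expect_equal(round(unname(pred), 3), 19.800)
    expect_equal(round(unname(deltaTR(m["Chonglou saponin VI", "col2"],
                                      pred)), 3), 1.811)

    # RR = 1 predicts the reference time exactly, in both modes
    expect_equal(unname(rrPredict(rrm, 27.161, "Chonglou saponin II")),
                 27.161)
    adj <- adjustedRRModel(computeStR(tab), "Chonglou saponin II", 2.7)
    expect_equal(unname(rrPredict(adj, 27.161, "Chonglou saponin II")),
                 27.161)

    # adjusted with t0 = 0 degenerates to the unadjusted form
    st <- computeStR(tab)
    adj0 <- rrModel(stR(st) / stR(st)[["Chonglou saponin II"]],
                    "Chonglou saponin II", t0 = 0, adjusted = TRUE)
    un0 <- rrModel(stR(st) / stR(st)[["Chonglou saponin II"]],
                   "Chonglou saponin II")
    expect_equal(rrPredict(adj0, 27.161), rrPredict(un0, 27.161))

    expect_error(rrPredict(rrModel(c(a = 0.5, b = 1), "b",
                                   adjusted = FALSE), 10, "c"), "c")
    expect_error(rrModel(c(a = 0.5, b = 1), "b", adjusted = TRUE),
                 "dead time")
})

test_that("method evaluation summarizes a deviation panel consistently", {
    set.seed(8)
    d <- matrix(abs(rnorm(15, 0.3, 0.2)), 3,
                dimnames = list(letters[1:3], paste0("c", 1:5)))
    rep <- evaluateMethod(d, tRLimit = 0.5, method = "lctrs_two_point")
    # internal consistency against a brute-force recomputation
    expect_equal(rep@maxDeltaTR, max(as.vector(d)))
    expect_equal(rep@meanDeltaTR, sum(d) / length(d))
    expect_equal(rep@positiveColumns,
                 sum(vapply(seq_len(ncol(d)),
                            function(j) all(d[, j] <= 0.5), logical(1))))
    expect_match(rep@notes, "resolution")

    # exact predictions: max = mean = 0, every column positive
    z <- matrix(0, 2, 4, dimnames = list(c("a", "b"), paste0("c", 1:4)))
    rz <- evaluateMethod(z, 0.5, "lctrs_multi_point")
    expect_equal(rz@maxDeltaTR, 0)
    expect_identical(rz@positiveColumns, 4L)

    one <- matrix(0.37, 1, 1, dimnames = list("a", "c1"))
    ro <- evaluateMethod(one, 0.5, "rr_unadjusted")
    expect_equal(ro@maxDeltaTR, ro@meanDeltaTR)

    expect_error(evaluateMethod(matrix(numeric(0), 0, 0), 0.5,
                                "rr_unadjusted"), "empty")
})

test_that("the four-method comparison reproduces the Paridis ordering", {
    tab <- paridisRetention()
    st <- computeStR(tab)
    cmp <- compareAll(tab, paridisRR(), paridisReferencePair(st),
                      strt = st, t0 = 2.7)
    expect_equal(round(cmp$rr_unadjusted@maxDeltaTR, 3), 1.811)
    means <- vapply(cmp[c("lctrs_multi_point", "lctrs_two_point",
                          "rr_adjusted", "rr_unadjusted")],
                    function(x) x@meanDeltaTR, numeric(1))
    expect_lt(means[["lctrs_multi_point"]], means[["lctrs_two_point"]])
    expect_lt(means[["lctrs_two_point"]],
              min(means[["rr_adjusted"]], means[["rr_unadjusted"]]))
    expect_identical(cmp$ranking$method[1], "lctrs_multi_point")
    expect_error(compareAll(tab, paridisRR(), paridisReferencePair(st),
                            strt = st), "dead time")
})

test_that("affine panels separate the calibration and RR methods", {
    # exact affine maps with nonzero intercepts: calibration is exact,
    # one-point RR through the origin is not
    st <- setNames(c(10, 16, 24, 30), c("r1", "a", "b", "r2"))
    m <- sapply(1:6, function(j) (0.9 + 0.03 * j) * st + 1.5)
    dimnames(m) <- list(names(st), paste0("c", 1:6))
    tab <- RetentionTable(m)
    strt <- computeStR(tab)
    rrm <- rrModel(stR(strt) / stR(strt)[["b"]], "b")
    pair <- referencePair(strt, "r1", "r2")
    cmp <- compareAll(tab, rrm, pair, strt = strt, t0 = 1)
    expect_equal(cmp$lctrs_two_point@maxDeltaTR, 0, tolerance = 1e-9)
    expect_equal(cmp$lctrs_multi_point@maxDeltaTR, 0, tolerance = 1e-9)
    expect_gt(cmp$rr_unadjusted@maxDeltaTR, 0.01)

    # zero intercepts and a common slope: all four methods are exact
    m2 <- sapply(1:6, function(j) 1.05 * st)
    dimnames(m2) <- dimnames(m)
    tab2 <- RetentionTable(m2)
    strt2 <- computeStR(tab2)
    rrm2 <- rrModel(stR(strt2) / stR(strt2)[["b"]], "b")
    cmp2 <- compareAll(tab2, rrm2, referencePair(strt2, "r1", "r2"),
                       strt = strt2, t0 = 1)
    for (mth in c("rr_unadjusted", "rr_adjusted", "lctrs_two_point",
                  "lctrs_multi_point"))
        expect_equal(cmp2[[mth]]@maxDeltaTR, 0, tolerance = 1e-9)
})

test_that("RR is scale-invariant and calibration affine-equivariant", {
    set.seed(17)
    st <- setNames(c(10, 16, 24, 30), c("r1", "a", "b", "r2"))
    rr <- st / st[["b"]]
    tRef <- 25
    p1 <- rrPredict(rrModel(rr, "b"), tRef)
    p2 <- rrPredict(rrModel(rr, "b"), 3 * tRef)
    expect_equal(3 * p1, p2)

    # two-point calibration commutes with affine maps of the target axis
    tm <- c(11, 31.5)
    line1 <- fitTwoPoint(st[c("r1", "r2")], tm)
    line2 <- fitTwoPoint(st[c("r1", "r2")], 1.3 * tm + 2)
    expect_equal(1.3 * predict(line1, st) + 2, predict(line2, st),
                 tolerance = 1e-10)
})

test_that("multi-point beats two-point and RR on most synthetic panels", {
    better <- 0L
    beatsRR <- 0L
    for (s in 1:100) {
        sim <- generatePanel(panelSpec(seed = 5000 + s))
        strt <- computeStR(sim$table)
        rrm <- rrModel(stR(strt) / stR(strt)[["Chonglou saponin II"]],
                       "Chonglou saponin II")
        pair <- referencePair(strt, "Chonglou saponin VII",
                              "Chonglou saponin I")
        cmp <- compareAll(sim$table, rrm, pair, strt = strt, t0 = 2.7)
        better <- better +
            (cmp$lctrs_multi_point@meanDeltaTR <=
             cmp$lctrs_two_point@meanDeltaTR)
        beatsRR <- beatsRR +
            (cmp$lctrs_multi_point@meanDeltaTR <
             cmp$rr_unadjusted@meanDeltaTR)
    }
    expect_gte(better, 90L)
    expect_gte(beatsRR, 90L)
})
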