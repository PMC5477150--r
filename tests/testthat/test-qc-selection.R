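test_that("column fits against St_R reproduce the Paridis panel numbers", {
    tab <- paridisRetention()
    strt <- computeStR(tab)
    # the published col4 coefficients arise from the published (3 d.p.)
    # St_R abscissa
    printed <- standardRetention(
        setNames(c(19.803, 22.110, 30.319, 33.035), paridisCompounds),
        columnIds(tab))
    f4 <- fitColumnVsStR(tab, printed, "col4")
    expect_equal(round(slope(f4@line), 4), 1.1038)
    expect_equal(round(intercept(f4@line), 4), -1.1075)
    expect_true(corrCoef(f4) > 0.99)

    # panel-wide mean correlation: 0.99922 computed vs 0.9993 printed
    # from unrounded raw data; agreement to one unit in the 4th decimal
    rs <- vapply(columnIds(tab),
                 function(cc) corrCoef(fitColumnVsStR(tab, strt, cc)),
                 numeric(1))
    expect_lt(abs(mean(rs) - 0.9993), 1e-4)

    # an exactly affine column has r = 1 and zero residuals
    m <- retentionTimes(tab)
    m[, "col1"] <- 1.07 * stR(strt) - 0.3
    aff <- fitColumnVsStR(RetentionTable(m), strt, "col1")
    expect_equal(corrCoef(aff), 1, tolerance = 1e-12)
    expect_equal(max(aff@residuals), 0, tolerance = 1e-10)

    expect_error(fitColumnVsStR(tab, strt, "colX"), "unknown")
})

test_that("a clean panel is left untouched and exclusion is idempotent", {
    sim <- generatePanel(panelSpec(seed = 101))
    rep1 <- detectOutliers(sim$table)
    expect_identical(nrow(rep1@excludedColumns), 0L)
    expect_identical(nrow(rep1@excludedCompounds), 0L)
    expect_equal(stR(rep1@finalStR), stR(computeStR(sim$table)))

    # re-running on the retained panel changes nothing
    rep2 <- detectOutliers(sim$table[, rep1@retainedColumns])
    expect_equal(stR(rep2@finalStR), stR(rep1@finalStR))
})

test_that("a shuffled column destroys linearity and is excluded", {
    sim <- generatePanel(panelSpec(seed = 202, nShuffled = 1))
    bad <- sim$truth$shuffledColumns
    rep <- detectOutliers(sim$table)
    expect_true(bad %in% rep@excludedColumns$column)
    expect_false(bad %in% columnsUsed(rep@finalStR))
})

test_that("a compound offset on 40% of columns is recovered", {
    sim <- generatePanel(panelSpec(seed = 303,
                                   offsetCompound = "Chonglou saponin VI"))
    rep <- detectOutliers(sim$table)
    expect_true("Chonglou saponin VI" %in% rep@excludedCompounds$compound)
    expect_false("Chonglou saponin VI" %in% compounds(rep@finalStR))
    # final St_R of the retained compounds is computed from retained
    # columns only
    expect_true(all(compounds(rep@finalStR) %in%
                    setdiff(rownames(retentionTimes(sim$table)),
                            "Chonglou saponin VI")))
})

test_that("reference-pair selection picks the published Paridis pair", {
    tab <- paridisRetention()
    sel <- selectReferencePair(tab)
    expect_identical(sel$pair@first, "Chonglou saponin VII")
    expect_identical(sel$pair@second, "Chonglou saponin I")
    expect_equal(tRCoverage(sel$pair), 1.0)
    expect_identical(nrow(sel$ranking), 6L)  # C(4,2) pairs ranked

    # two candidates only: that pair, coverage 1
    st <- computeStR(tab)
    two <- selectReferencePair(tab, st,
                               candidates = c("Chonglou saponin VII",
                                              "Chonglou saponin I"))
    expect_equal(tRCoverage(two$pair), 1.0)

    expect_error(selectReferencePair(tab, coverageMin = 1.01),
                 "coverageMin")
})

test_that("selection skips pairs containing a planted nonlinear compound", {
    # the last-eluting compound of a six-compound profile is nonlinear
    # on 40% of columns (its extreme position gives it high leverage, so
    # a 4 min shift is needed before its residuals stand out); QC flags
    # it and the best remaining high-coverage pair is returned
    st6 <- setNames(c(8, 13, 19, 24, 30, 36), paste0("cmp", 1:6))
    sim <- generatePanel(panelSpec(seed = 404, stRTrue = st6,
                                   offsetCompound = "cmp6",
                                   offsetMagnitude = 4,
                                   offsetFraction = 0.4))
    qc <- detectOutliers(sim$table)
    expect_true("cmp6" %in% qc@excludedCompounds$compound)
    sel <- selectReferencePair(sim$table, coverageMin = 0.5,
                               excludeCompounds =
                                   qc@excludedCompounds$compound)
    expect_false("cmp6" %in% c(sel$pair@first, sel$pair@second))
})

test_that("pair ranking agrees with an exhaustive lm-based oracle", {
    sim <- generatePanel(panelSpec(seed = 505,
        stRTrue = setNames(c(8, 13, 19, 24, 30, 36), letters[1:6]),
        nColumns = 8))
    tab <- sim$table
    strt <- computeStR(tab)
    sel <- selectReferencePair(tab, strt, coverageMin = 0)
    m <- retentionTimes(tab)
    st <- stR(strt)
    oracle <- do.call(rbind, combn(letters[1:6], 2, function(p) {
        p <- p[order(st[p])]
        ds <- vapply(colnames(m), function(cc) {
            fit <- stats::lm(m[p, cc] ~ st[p])
            pred <- stats::coef(fit)[1] + stats::coef(fit)[2] *
                st[setdiff(letters[1:6], p)]
            mean(abs(m[setdiff(letters[1:6], p), cc] - pred))
        }, numeric(1))
        data.frame(first = p[1], second = p[2], meanDeltaTR = mean(ds))
    }, simplify = FALSE))
    oracle <- oracle[order(oracle$meanDeltaTR), ]
    expect_equal(sel$ranking$first, oracle$first)
    expect_equal(sel$ranking$second, oracle$second)
    expect_equal(sel$ranking$meanDeltaTR, oracle$meanDeltaTR,
                 tolerance = 1e-9)
})

test_that("the subsampling study is seeded, capped and exact at k = N", {
    tab <- paridisRetention()
    s1 <- subsampleStudy(tab, kValues = c(1, 30), nDraws = c(40, 5),
                         seed = 9)
    # k = 1 draws capped at choose(30, 1) = 30; k = N has one draw, sd 0
    expect_equal(s1@summary$nDraws, c(30, 1))
    expect_equal(s1@summary$sdDeltaTR[2], 0)

    s2 <- subsampleStudy(tab, kValues = c(1, 30), nDraws = c(40, 5),
                         seed = 9)
    expect_identical(s1@summary, s2@summary)

    expect_error(subsampleStudy(tab, kValues = 31, seed = 1), "exceed")
    expect_error(subsampleStudy(tab, kValues = 5, nDraws = 10), "seed")
})

test_that("mean deviation shrinks with panel size on synthetic panels", {
    sim <- generatePanel(panelSpec(seed = 606))
    ss <- subsampleStudy(sim$table, kValues = c(2, 5, 10, 20, 30),
                         nDraws = c(60, 60, 60, 60, 1), seed = 7)
    s <- ss@summary
    expect_true(all(diff(s$meanDeltaTR) <= head(s$sdDeltaTR, -1)))
    expect_lt(s$meanDeltaTR[nrow(s)], s$meanDeltaTR[1])
})

test_that("fitted per-column parameters recover the generator's truth", {
    # 20 replicates here as a fast guard; the full 200-replicate study
    # runs in the acceptance suite
    hits <- 0L; total <- 0L
    for (rep in 1:20) {
        sim <- generatePanel(panelSpec(seed = 7000 + rep))
        truth <- sim$truth
        strtTrue <- standardRetention(truth$stRTrue, "truth")
        st <- truth$stRTrue
        sxx <- sum((st - mean(st))^2)
        seA <- 0.05 / sqrt(sxx)
        seB <- 0.05 * sqrt(1 / length(st) + mean(st)^2 / sxx)
        for (cc in columnIds(sim$table)) {
            f <- fitColumnVsStR(sim$table, strtTrue, cc)
            okA <- abs(slope(f@line) - truth$slopes[[cc]]) <= 3 * seA
            okB <- abs(intercept(f@line) - truth$intercepts[[cc]]) <= 3 * seB
            hits <- hits + (okA && okB)
            total <- total + 1L
        }
    }
    expect_gte(hits / total, 0.95)
})
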