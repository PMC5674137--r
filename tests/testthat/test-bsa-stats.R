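test_that("delta and |delta| propagate signs, extremes and missingness", {
    pv <- PooledVariants("s1", 1:4, "A", "G",
                         adRefA = c(0L, 10L, 0L, 0L),
                         adAltA = c(20L, 10L, 20L, 0L),
                         adRefB = c(20L, 10L, 6L, 10L),
                         adAltB = c(0L, 10L, 14L, 10L))
    expect_equal(deltaIndex(pv), c(1, 0, 0.3, NA))
    expect_equal(absDeltaIndex(pv), c(1, 0, 0.3, NA))
    # |delta| == abs(delta) across random simulator output
    sim <- simulateCross(tinyCross(seed = 5L))
    expect_identical(absDeltaIndex(simVariants(sim)),
                     abs(deltaIndex(simVariants(sim))))
})

test_that("window grid enumerates, truncates and degenerates correctly", {
    g <- makeWindowGrid(c(s = 300000))
    expect_length(g, 15L)
    expect_equal(GenomicRanges::start(g)[1:2], c(1L, 20001L))
    expect_equal(GenomicRanges::end(g)[1:2], c(200000L, 220000L))
    expect_equal(GenomicRanges::start(g)[15], 280001L)
    expect_equal(GenomicRanges::end(g)[15], 300000L)

    # scaffold shorter than one window: every window truncated at the end
    g2 <- makeWindowGrid(c(s = 100000))
    expect_length(g2, 5L)
    expect_equal(GenomicRanges::start(g2), seq(1L, 80001L, by = 20000L))
    expect_true(all(GenomicRanges::end(g2) == 100000L))

    g3 <- makeWindowGrid(c(s = 1), windowSize = 1, step = 1)
    expect_length(g3, 1L)
    expect_equal(GenomicRanges::width(g3), 1L)

    expect_error(makeWindowGrid(c(s = 1e5), windowSize = 0), "positive")
    expect_error(makeWindowGrid(c(s = 1e5), windowSize = 1e4, step = 2e4),
                 "must not exceed")
})

test_that("window means match a brute-force per-window rescan", {
    sl <- c(a = 2e5, b = 15e4, c = 1e5, d = 9e4, e = 5e4)
    pv <- randomVariants(1000L, sl, seed = 11L)
    ws <- windowStatistics(pv, makeWindowGrid(sl))
    got <- as.data.frame(S4Vectors::mcols(windowRanges(ws)))
    want <- bruteWindowStats(pv, makeWindowGrid(sl))
    expect_identical(got$nSNPs, want$nSNPs)
    for (cc in c("meanIndexA", "meanIndexB", "meanDelta", "meanAbsDelta"))
        expect_equal(got[[cc]], want[[cc]], tolerance = 1e-12)
})

test_that("window means respect bounds and the triangle inequality", {
    pv <- PooledVariants("s1", c(10L, 50L), "A", "G",
                         adRefA = c(16L, 2L), adAltA = c(4L, 18L),
                         adRefB = c(8L, 18L), adAltB = c(12L, 2L))
    ws <- windowStatistics(pv, makeWindowGrid(c(s1 = 200000)))
    w1 <- windowRanges(ws)[1L]
    expect_equal(w1$nSNPs, 2L)
    expect_equal(w1$meanAbsDelta, mean(c(0.4, 0.8)))   # |0.2-0.6|, |0.9-0.1|
    expect_equal(w1$meanDelta, mean(c(-0.4, 0.8)))

    # empty window: all statistics missing
    pv2 <- PooledVariants("s1", 250000L, "A", "G", 10L, 10L, 10L, 10L)
    ws2 <- windowStatistics(pv2, makeWindowGrid(c(s1 = 300000)))
    w <- windowRanges(ws2)
    expect_identical(w$nSNPs[1L], 0L)
    expect_true(all(is.na(S4Vectors::mcols(w[1L])[, -1])))

    # property over random data: min <= mean|D| <= max, mean|D| >= |meanD|
    sl <- c(x = 3e5)
    pv3 <- randomVariants(400L, sl, seed = 21L)
    ws3 <- windowStatistics(pv3, makeWindowGrid(sl))
    md <- S4Vectors::mcols(windowRanges(ws3))
    d <- deltaIndex(pv3)
    hits <- GenomicRanges::findOverlaps(windowRanges(ws3), variantRanges(pv3))
    for (i in unique(S4Vectors::queryHits(hits))) {
        vals <- abs(d[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        expect_gte(md$meanAbsDelta[i], min(vals) - 1e-12)
        expect_lte(md$meanAbsDelta[i], max(vals) + 1e-12)
        expect_gte(md$meanAbsDelta[i], abs(md$meanDelta[i]) - 1e-12)
    }

    # minSnpsPerWindow marks thin windows missing
    ws4 <- windowStatistics(pv, makeWindowGrid(c(s1 = 200000)),
                            minSnpsPerWindow = 3L)
    expect_true(all(is.na(windowRanges(ws4)$meanAbsDelta)))
    expect_identical(windowRanges(ws4)$nSNPs[1L], 2L)
})

test_that("quantile thresholds count tails, honor symmetry, stay monotone", {
    # 1000 windows with |delta| = i/1000: top 0.5% leaves exactly 5 above
    sl <- c(s = 1000L * 20L)
    grid <- makeWindowGrid(sl, windowSize = 20L, step = 20L)
    vals <- seq_len(1000L) / 1000L
    pv <- PooledVariants("s", GenomicRanges::start(grid) + 1L, "A", "G",
                         adRefA = 1000L - as.integer(vals * 1000),
                         adAltA = as.integer(vals * 1000),
                         adRefB = 1000L, adAltB = 0L, seqlengths = sl)
    ws <- windowStatistics(pv, grid)
    thr <- quantileThresholds(ws, "abs_delta", upperQ = 0.005)
    expect_identical(sum(flagWindows(ws, thr)), 5L)

    # degenerate ties: constant statistic flags nothing under strict ">"
    pvC <- PooledVariants("s", GenomicRanges::start(grid) + 1L, "A", "G",
                          adRefA = 6L, adAltA = 4L, adRefB = 10L, adAltB = 0L,
                          seqlengths = sl)
    wsC <- windowStatistics(pvC, grid)
    thrC <- quantileThresholds(wsC, "abs_delta", upperQ = 0.01)
    expect_equal(thrC@upperValue, 0.4)
    expect_identical(sum(flagWindows(wsC, thrC)), 0L)

    # symmetric signed deltas: lower threshold mirrors the upper
    alt <- rep(c(200L, 800L), length.out = 1000L)
    pvS <- PooledVariants("s", GenomicRanges::start(grid) + 1L, "A", "G",
                          adRefA = 1000L - alt, adAltA = alt,
                          adRefB = 500L, adAltB = 500L, seqlengths = sl)
    wsS <- windowStatistics(pvS, grid)
    thrS <- quantileThresholds(wsS, "delta", upperQ = 0.25, lowerQ = 0.25)
    expect_equal(thrS@lowerValue, -thrS@upperValue)

    # raising upperQ never raises the threshold
    qs <- c(0.002, 0.005, 0.01, 0.05, 0.2)
    th <- vapply(qs, function(q)
        quantileThresholds(ws, "abs_delta", upperQ = q)@upperValue,
        numeric(1L))
    expect_true(all(diff(th) <= 1e-12))

    # all-missing statistics refuse quantiles
    pvE <- PooledVariants("s", 10L, "A", "G", 10L, 10L, 0L, 0L,
                          seqlengths = sl)
    wsE <- windowStatistics(pvE, grid)
    expect_error(quantileThresholds(wsE, "abs_delta"), "missing")
})
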