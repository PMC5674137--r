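test_that("the same seed reproduces a bit-identical dataset", {
    a <- simulateCross(tinyCross(seed = 7L))
    b <- simulateCross(tinyCross(seed = 7L))
    expect_equal(as.data.frame(simVariants(a)), as.data.frame(simVariants(b)))
    expect_identical(simTruth(a)$phenotype, simTruth(b)$phenotype)
    expect_identical(simTruth(a)$breakpoints, simTruth(b)$breakpoints)
    c <- simulateCross(tinyCross(seed = 8L))
    expect_false(identical(as.data.frame(simVariants(a)),
                           as.data.frame(simVariants(c))))
    # write-twice determinism: same seed, byte-identical bundle
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    f1 <- writeSimBundle(a, d1); f2 <- writeSimBundle(b, d2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("parental heterozygosity limits pin haplotypes", {
    set.seed(1)
    cfg0 <- tinyCross(parentHeterozygosity = 0)
    p0 <- simulateParents(cfg0)
    for (i in 1:2) {
        # QTL site is forced heterozygous in parent A; all else homozygous
        hom <- p0$parentA[[i]][, 1L] == p0$parentA[[i]][, 2L]
        if (i == p0$qtlScaffold) hom <- hom[-p0$qtlSite]
        expect_true(all(hom))
        expect_true(all(p0$parentB[[i]][, 1L] == p0$parentB[[i]][, 2L]))
    }
    cfg1 <- tinyCross(parentHeterozygosity = 1)
    p1 <- simulateParents(cfg1)
    for (i in 1:2) {
        expect_true(all(p1$parentA[[i]][, 1L] != p1$parentA[[i]][, 2L]))
        # parent B is forced homozygous rr at the trait locus in an Rr x rr
        # cross; every other site is heterozygous
        hetB <- p1$parentB[[i]][, 1L] != p1$parentB[[i]][, 2L]
        if (i == p1$qtlScaffold) hetB <- hetB[-p1$qtlSite]
        expect_true(all(hetB))
    }
    expect_error(simulateParents(tinyCross(snpDensity = 0)), "zero")
})

test_that("without recombination every gamete is an intact haplotype", {
    set.seed(2)
    cfg <- tinyCross(recombinationRate = 0, parentHeterozygosity = 1)
    par <- simulateParents(cfg)
    off <- simulateOffspring(par, cfg)
    for (i in 1:2) {
        g <- off$gameteA[[i]]
        h <- par$parentA[[i]]
        match1 <- colSums(g == h[, 1L]) == nrow(g)
        match2 <- colSums(g == h[, 2L]) == nrow(g)
        expect_true(all(match1 | match2))
    }
})

test_that("a dominant Rr x rr cross segregates 1:1 at full penetrance", {
    set.seed(3)
    cfg <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 5e4,
                          qtlPosition = 2.5e4, nOffspring = 500L,
                          nOffspringPerPool = c(10L, 10L), penetrance = 1)
    par <- simulateParents(cfg)
    off <- simulateOffspring(par, cfg)
    nRed <- sum(off$phenotype)
    expect_gte(nRed, qbinom(0.005, 500, 0.5))
    expect_lte(nRed, qbinom(0.995, 500, 0.5))
    # RrXRr segregates 3:1
    cfg2 <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 5e4,
                           qtlPosition = 2.5e4, nOffspring = 500L,
                           nOffspringPerPool = c(10L, 10L),
                           crossType = "RrXRr")
    par2 <- simulateParents(cfg2)
    off2 <- simulateOffspring(par2, cfg2)
    expect_gte(sum(off2$phenotype), qbinom(0.005, 500, 0.75))
    expect_lte(sum(off2$phenotype), qbinom(0.995, 500, 0.75))
})

test_that("crossover counts per gamete behave like a Poisson process", {
    set.seed(4)
    cfg <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 1e6,
                          snpDensity = 0.002, qtlPosition = 5e5,
                          parentHeterozygosity = 1, recombinationRate = 50,
                          nOffspring = 400L, nOffspringPerPool = c(10L, 10L))
    par <- simulateParents(cfg)
    off <- simulateOffspring(par, cfg)
    h <- par$parentA[[1L]]
    pos <- par$positions[[1L]]
    # with every site heterozygous the parental origin is readable site by
    # site; switches of origin along the scaffold are observed crossovers
    counts <- apply(off$gameteA[[1L]], 2L, function(g) {
        origin <- ifelse(g == h[, 1L], 1L, 2L)
        sum(diff(origin) != 0L)
    })
    span <- (max(pos) - min(pos)) / cfg@scaffoldLength
    lambda <- cfg@recombinationRate * cfg@scaffoldLength / 1e6 / 100 * span
    # mean within z-bounds at alpha = 0.001
    z <- abs(mean(counts) - lambda) / sqrt(lambda / length(counts))
    expect_lt(z, qnorm(0.9995))
    # dispersion index near 1 (chi-square bounds at alpha = 0.001)
    disp <- var(counts) * (length(counts) - 1L) / mean(counts)
    expect_gt(disp, qchisq(0.0005, length(counts) - 1L))
    expect_lt(disp, qchisq(0.9995, length(counts) - 1L))
})

test_that("pooled sequencing recovers the Mendelian signal at the locus", {
    # Rr x rr, full penetrance, parental reference, no sequencing error,
    # deep coverage: |Delta| at the trait site approaches 0.5
    cfg <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 1e5,
                          snpDensity = 0.001, qtlPosition = 5e4,
                          nOffspring = 120L, nOffspringPerPool = c(28L, 27L),
                          meanDepth = 400, sequencingError = 0,
                          referenceMode = "parental", penetrance = 1,
                          seed = 31L)
    sim <- simulateCross(cfg)
    gr <- variantRanges(simVariants(sim))
    at <- which(GenomicRanges::start(gr) == 5e4)
    d <- deltaIndex(simVariants(sim))[at]
    expect_equal(abs(d), 0.5, tolerance = 0.08)
    # a fixed difference is impossible: indices stay in [0,1]
    idx <- c(snpIndex(simVariants(sim), "A"), snpIndex(simVariants(sim), "B"))
    expect_true(all(idx >= 0 & idx <= 1, na.rm = TRUE))
})

test_that("pool construction fails cleanly when offspring run short", {
    cfg <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 5e4,
                          qtlPosition = 2.5e4, nOffspring = 40L,
                          nOffspringPerPool = c(20L, 20L), seed = 17L)
    # Rr x rr gives ~20/20; forcing all-carrier pools must fail sometimes:
    # use penetrance 1 and ask for 20+20 out of 40 -> any imbalance errors
    fails <- 0L
    for (s in 1:5) {
        cfg@seed <- s
        fails <- fails + tryCatch({ simulateCross(cfg); 0L },
                                  error = function(e) {
                                      expect_match(conditionMessage(e),
                                                   "not enough offspring")
                                      1L
                                  })
    }
    expect_gt(fails, 0L)
})

test_that("mosaic references attenuate windowed signed Delta but not |Delta|", {
    # near the locus, per-site Delta keeps its magnitude but flips sign at
    # reference breakpoints; window-averaging then cancels the signed value
    diffs <- vapply(1:20, function(r) {
        cfg <- CrossSimConfig(nScaffolds = 1L, scaffoldLength = 1e6,
                              qtlPosition = 5e5, nOffspring = 80L,
                              nOffspringPerPool = c(28L, 27L),
                              referenceMode = "mosaic",
                              mosaicSwitchRate = 20,
                              seed = 7000L + r)
        sim <- simulateCross(cfg)
        ws <- windowStatistics(simVariants(sim),
                               makeWindowGrid(simSeqlengths(sim)))
        w <- windowRanges(ws)
        near <- GenomicRanges::start(w) <= 5e5 & GenomicRanges::end(w) >= 5e5
        mean(w$meanAbsDelta[near], na.rm = TRUE) -
            mean(abs(w$meanDelta[near]), na.rm = TRUE)
    }, numeric(1L))
    # paired one-sided test: |Delta| windows carry more signal
    expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.05)
    expect_gt(mean(diffs), 0.05)
})

test_that("the called interval recovers the true locus in most replicates", {
    hits <- vapply(1:10, function(s) {
        sim <- simulateCross(CrossSimConfig(seed = 4000L + s))
        res <- runQtlseq(simVariants(sim), seqlengths = simSeqlengths(sim))
        coversQtl(sim, res$intervals)
    }, logical(1L))
    expect_gte(sum(hits), 8L)
})
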