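# Shared fixture builders: everything is generated in code at test time.

# random pooled variants spread over the given scaffolds
randomVariants <- function(n, seqlengths, seed = 1L, depth = 30L) {
    set.seed(seed)
    scaf <- sample(names(seqlengths), n, replace = TRUE)
    pos <- vapply(scaf, function(s) sample.int(seqlengths[[s]], 1L),
                  integer(1L), USE.NAMES = FALSE)
    dA <- rpois(n, depth); dB <- rpois(n, depth)
    aA <- rbinom(n, dA, runif(n)); aB <- rbinom(n, dB, runif(n))
    PooledVariants(scaffold = scaf, position = pos, ref = "A", alt = "G",
                   adRefA = dA - aA, adAltA = aA,
                   adRefB = dB - aB, adAltB = aB,
                   seqlengths = seqlengths)
}

# small, fast cross configuration for unit tests
tinyCross <- function(...) {
    CrossSimConfig(nScaffolds = 2L, scaffoldLength = 4e5, qtlPosition = 2e5,
                   nOffspring = 60L, nOffspringPerPool = c(12L, 12L), ...)
}

# brute-force window means: rescan every variant for every window
bruteWindowStats <- function(variants, grid) {
    vr <- variantRanges(variants)
    d <- deltaIndex(variants)
    out <- data.frame(nSNPs = integer(length(grid)),
                      meanIndexA = NA_real_, meanIndexB = NA_real_,
                      meanDelta = NA_real_, meanAbsDelta = NA_real_)
    for (i in seq_along(grid)) {
        sel <- as.character(GenomicRanges::seqnames(vr)) ==
            as.character(GenomicRanges::seqnames(grid[i])) &
            GenomicRanges::start(vr) >= GenomicRanges::start(grid[i]) &
            GenomicRanges::start(vr) <= GenomicRanges::end(grid[i])
        out$nSNPs[i] <- sum(sel)
        mn <- function(v) if (any(!is.na(v[sel]))) mean(v[sel], na.rm = TRUE)
            else NA_real_
        out$meanIndexA[i] <- mn(vr$indexA)
        out$meanIndexB[i] <- mn(vr$indexB)
        out$meanDelta[i] <- mn(d)
        out$meanAbsDelta[i] <- mn(abs(d))
    }
    out
}

qtlPoint <- function(sim) {
    GenomicRanges::GRanges(simTruth(sim)$qtlScaffold,
                           IRanges::IRanges(simTruth(sim)$qtlPosition,
                                            width = 1L))
}

coversQtl <- function(sim, intervals) {
    length(GenomicRanges::findOverlaps(qtlPoint(sim), intervals)) > 0L
}
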