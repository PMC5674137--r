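#' Detection-power comparison of |Delta| versus signed Delta windows
#'
#' Repeats the full simulate-then-analyse cycle: each replicate draws a
#' pooled-sequencing dataset from `config` (seeded `baseSeed + replicate`),
#' runs the pipeline once per method on the same data, and records whether
#' any called candidate interval covers the true trait locus. The two
#' methods flag the same total tail mass (`upperQ` for `"abs_delta"`;
#' `upperQ/2` in each tail for `"delta"`), so the comparison isolates the
#' statistic itself. Under a mosaic reference the pseudoexchange sign-flips
#' cancel the windowed signed Delta but leave |Delta| intact, which is the
#' asymmetry this experiment quantifies.
#'
#' @param config a [CrossSimConfig]; its `seed` slot is ignored here.
#' @param nReplicates number of simulated datasets (default 50).
#' @param methods window statistics to compare.
#' @param baseSeed replicate r uses seed `baseSeed + r`.
#' @param filterPolicy,windowSize,step,upperQ,sparsity,minSnpsPerWindow
#'   passed to [runQtlseq()].
#' @return a `data.frame` with one row per replicate x method: `replicate`,
#'   `method`, `detected`, `nIntervals`, `totalWidthBp`, `coveringWidthBp`
#'   (width of the interval covering the locus, `NA` if undetected).
#' @examples
#' cfg <- CrossSimConfig(nScaffolds = 2L, scaffoldLength = 4e5,
#'                       qtlPosition = 2e5, nOffspring = 60L,
#'                       nOffspringPerPool = c(12L, 12L))
#' tab <- powerExperiment(cfg, nReplicates = 3, baseSeed = 5,
#'                        sparsity = SparsityPolicy(minSnps = 3))
#' detectionRates(tab)
#' @seealso [detectionRates()], [pairedDetectionTest()]
#' @export
powerExperiment <- function(config, nReplicates = 50L,
                            methods = c("delta", "abs_delta"),
                            baseSeed = 1L,
                            filterPolicy = FilterPolicy(),
                            windowSize = 200000L, step = 20000L,
                            upperQ = 0.005,
                            sparsity = SparsityPolicy(),
                            minSnpsPerWindow = 1L) {
    stopifnot(is(config, "CrossSimConfig"))
    methods <- match.arg(methods, c("delta", "abs_delta"),
                         several.ok = TRUE)
    if (config@snpDensity <= 0)
        stop("empty input: 'snpDensity' is zero, no sites to simulate")
    rows <- vector("list", nReplicates * length(methods))
    ri <- 0L
    for (r in seq_len(nReplicates)) {
        cfg <- config
        cfg@seed <- as.integer(baseSeed + r)
        sim <- simulateCross(cfg)
        qtl <- GRanges(sim@truth$qtlScaffold,
                       IRanges(sim@truth$qtlPosition, width = 1L))
        for (m in methods) {
            res <- runQtlseq(simVariants(sim), seqlengths = sim@seqlengths,
                             statistic = m, filterPolicy = filterPolicy,
                             windowSize = windowSize, step = step,
                             upperQ = upperQ, sparsity = sparsity,
                             minSnpsPerWindow = minSnpsPerWindow)
            hit <- findOverlaps(qtl, res$intervals, ignore.strand = TRUE)
            covering <- if (length(hit))
                sum(width(res$intervals[subjectHits(hit)])) else NA_real_
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                replicate = r, method = m,
                detected = length(hit) > 0L,
                nIntervals = length(res$intervals),
                totalWidthBp = res$summary$totalFilteredBp,
                coveringWidthBp = covering)
        }
    }
    do.call(rbind, rows)
}

#' Detection rate per method with exact binomial confidence bounds
#'
#' @param tab output of [powerExperiment()].
#' @param conf confidence level (default 0.95).
#' @return a `data.frame`: method, nReplicates, nDetected, rate, lower,
#'   upper (Clopper-Pearson bounds).
#' @export
detectionRates <- function(tab, conf = 0.95) {
    out <- lapply(split(tab, tab$method), function(d) {
        bt <- binom.test(sum(d$detected), nrow(d), conf.level = conf)
        data.frame(method = d$method[1L], nReplicates = nrow(d),
                   nDetected = sum(d$detected),
                   rate = unname(bt$estimate),
                   lower = bt$conf.int[1L], upper = bt$conf.int[2L])
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Paired one-sided test that one method detects the locus more often
#'
#' Replicates are paired (both methods analyse the same simulated data), so
#' the comparison uses only the discordant pairs: an exact one-sided
#' binomial (sign) test of whether replicates detected by `better` but not
#' `worse` outnumber the converse. With no discordant pairs the p-value
#' is 1.
#'
#' @param tab output of [powerExperiment()] containing both methods.
#' @param better,worse method names (default: `"abs_delta"` over
#'   `"delta"`).
#' @return a list: `nBetterOnly`, `nWorseOnly`, `pValue`.
#' @export
pairedDetectionTest <- function(tab, better = "abs_delta", worse = "delta") {
    wide <- merge(tab[tab$method == better, c("replicate", "detected")],
                  tab[tab$method == worse, c("replicate", "detected")],
                  by = "replicate", suffixes = c(".b", ".w"))
    b <- sum(wide$detected.b & !wide$detected.w)
    w <- sum(!wide$detected.b & wide$detected.w)
    p <- if (b + w == 0L) 1 else
        binom.test(b, b + w, alternative = "greater")$p.value
    list(nBetterOnly = b, nWorseOnly = w, pValue = p)
}
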