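#' Build a sliding-window grid over scaffolds
#'
#' Windows of `windowSize` bp advanced by `step` bp: on each scaffold they
#' start at 1, 1+step, 1+2*step, ... for every start not beyond the scaffold
#' end, and each window ends at `min(start + windowSize - 1, scaffoldLength)`
#' — windows overhanging the scaffold end are truncated, never discarded.
#'
#' @param seqlengths named vector of scaffold lengths in bp
#'   (see [readScaffoldLengths()]).
#' @param windowSize window width in bp (default 200 kb).
#' @param step window increment in bp (default 20 kb); must not exceed
#'   `windowSize`.
#' @return a `GRanges` of empty window shells with seqlengths set.
#' @examples
#' g <- makeWindowGrid(c(s1 = 300000))
#' length(g)        # 15
#' range(width(g))
#' @seealso [windowStatistics()]
#' @export
makeWindowGrid <- function(seqlengths, windowSize = 200000L, step = 20000L) {
    windowSize <- as.integer(windowSize); step <- as.integer(step)
    if (is.na(windowSize) || windowSize < 1L || is.na(step) || step < 1L)
        stop("'windowSize' and 'step' must be positive")
    if (step > windowSize) stop("'step' must not exceed 'windowSize'")
    if (is.null(names(seqlengths)) || any(seqlengths < 1))
        stop("'seqlengths' must be a named vector of positive lengths")
    sl <- as.integer(seqlengths)
    starts <- lapply(sl, function(len) seq.int(1L, len, by = step))
    ends <- Map(function(st, len) pmin(st + windowSize - 1L, len),
                starts, sl)
    GRanges(rep(names(seqlengths), lengths(starts)),
            IRanges(unlist(starts, use.names = FALSE),
                    unlist(ends, use.names = FALSE)),
            seqinfo = Seqinfo(names(seqlengths), sl))
}

#' Sliding-window means of SNP-index statistics
#'
#' Fills a window grid with arithmetic means, over the SNPs each window
#' contains, of the per-pool SNP-indices, the signed Delta(SNP-index) and
#' |Delta(SNP-index)|. A variant contributes to every window overlapping its
#' position (windowSize/step windows in the scaffold interior); missing
#' values never contribute to a mean. Windows with fewer than
#' `minSnpsPerWindow` SNPs have all statistics set missing.
#'
#' @param variants a [PooledVariants] object.
#' @param grid window shells from [makeWindowGrid()]; scaffolds absent from
#'   the grid are ignored with a warning.
#' @param windowSize,step used only when `grid` is `NULL`, in which case the
#'   grid is built from the variants' seqlengths.
#' @param minSnpsPerWindow windows with fewer SNPs get missing statistics
#'   (default 1, i.e. only empty windows are missing).
#' @return a [WindowStats-class] object.
#' @examples
#' pv <- PooledVariants("s1", c(10L, 50L), "A", "G",
#'                      adRefA = c(0L, 10L), adAltA = c(10L, 10L),
#'                      adRefB = c(10L, 10L), adAltB = c(10L, 0L))
#' ws <- windowStatistics(pv, makeWindowGrid(c(s1 = 200000)))
#' windowRanges(ws)$meanAbsDelta[1]   # mean of |1 - 0.5| and |0.5 - 0|
#' @export
windowStatistics <- function(variants, grid = NULL,
                             windowSize = 200000L, step = 20000L,
                             minSnpsPerWindow = 1L) {
    stopifnot(is(variants, "PooledVariants"))
    vr <- variantRanges(variants)
    if (is.null(grid)) {
        sl <- seqlengths(vr)
        if (!length(sl) || all(is.na(sl)))
            stop("no 'grid' given and variants carry no seqlengths")
        grid <- makeWindowGrid(sl, windowSize, step)
    } else {
        windowSize <- max(width(grid))
        step <- if (length(grid) > 1L) {
            st <- sort(unique(diff(sort(unique(start(grid))))))
            as.integer(st[1L])
        } else as.integer(windowSize)
        lost <- setdiff(unique(as.character(seqnames(vr))),
                        seqlevels(grid))
        if (length(lost))
            warning("variants on scaffold(s) absent from the grid: ",
                    paste(lost, collapse = ", "))
    }
    n <- length(grid)
    hits <- findOverlaps(grid, vr, ignore.strand = TRUE)
    q <- queryHits(hits); s <- subjectHits(hits)

    meanOf <- function(vals) {
        vv <- vals[s]; ok <- !is.na(vv)
        cnt <- tabulate(q[ok], nbins = n)
        tot <- numeric(n)
        if (any(ok)) {
            rs <- rowsum(vv[ok], q[ok])
            tot[as.integer(rownames(rs))] <- rs[, 1L]
        }
        out <- tot / cnt
        out[cnt == 0L] <- NA_real_
        out
    }
    d <- deltaIndex(variants)
    md <- DataFrame(nSNPs = tabulate(q, nbins = n),
                    meanIndexA = meanOf(vr$indexA),
                    meanIndexB = meanOf(vr$indexB),
                    meanDelta = meanOf(d),
                    meanAbsDelta = meanOf(abs(d)))
    thin <- md$nSNPs < as.integer(minSnpsPerWindow)
    for (cc in c("meanIndexA", "meanIndexB", "meanDelta", "meanAbsDelta"))
        md[[cc]][thin] <- NA_real_
    out <- grid
    mcols(out) <- md
    .WindowStats(windows = out, windowSize = as.integer(windowSize),
                 step = as.integer(step), poolNames = poolNames(variants))
}

.windowStat <- function(ws, statistic = c("abs_delta", "delta")) {
    statistic <- match.arg(statistic)
    md <- mcols(windowRanges(ws))
    if (statistic == "abs_delta") md$meanAbsDelta else md$meanDelta
}

#' Empirical quantile thresholds on window statistics
#'
#' Computes the realized threshold value(s) for flagging candidate windows:
#' `upperValue` is the (1 − upperQ) empirical quantile (linear
#' interpolation, `stats::quantile` type 7) of the non-missing window
#' statistics, so e.g. `upperQ = 0.005` marks the top 0.5% of
#' |Delta(SNP-index)| windows. For the signed statistic a `lowerQ` tail is
#' usually requested as well (e.g. top and lowermost 0.25%). Thresholds are
#' properties of the data at hand, not constants.
#'
#' @param ws a [WindowStats-class] object.
#' @param statistic `"abs_delta"` (default) or `"delta"`.
#' @param upperQ upper tail probability (default 0.005).
#' @param lowerQ lower tail probability, or `NULL`/`NA` for none.
#' @return a [ThresholdSet-class].
#' @examples
#' pv <- PooledVariants("s1", seq(5000L, 295000L, by = 1000L), "A", "G",
#'                      adRefA = 10L, adAltA = 10L, adRefB = 5L, adAltB = 15L)
#' ws <- windowStatistics(pv, makeWindowGrid(c(s1 = 300000)))
#' quantileThresholds(ws, "abs_delta", upperQ = 0.005)
#' @seealso [flagWindows()]
#' @export
quantileThresholds <- function(ws, statistic = c("abs_delta", "delta"),
                               upperQ = 0.005, lowerQ = NULL) {
    statistic <- match.arg(statistic)
    vals <- .windowStat(ws, statistic)
    vals <- vals[!is.na(vals)]
    if (!length(vals))
        stop("all window statistics are missing; cannot take quantiles")
    if (is.null(lowerQ)) lowerQ <- NA_real_
    upperValue <- unname(quantile(vals, 1 - upperQ, type = 7))
    lowerValue <- if (is.na(lowerQ)) NA_real_ else
        unname(quantile(vals, lowerQ, type = 7))
    .ThresholdSet(statistic = statistic, upperQ = as.numeric(upperQ),
                  lowerQ = as.numeric(lowerQ),
                  upperValue = upperValue, lowerValue = lowerValue)
}

#' Flag windows exceeding quantile thresholds
#'
#' Strict comparison: a window is flagged when its statistic is strictly
#' above the upper threshold, or strictly below the lower threshold when one
#' is set (so with a constant statistic no window is flagged). Windows with
#' missing statistics are never flagged.
#'
#' @param ws a [WindowStats-class] object.
#' @param thresholds a [ThresholdSet-class] from [quantileThresholds()].
#' @return logical vector parallel to `windowRanges(ws)`.
#' @seealso [callIntervals()]
#' @export
flagWindows <- function(ws, thresholds) {
    stopifnot(is(thresholds, "ThresholdSet"))
    vals <- .windowStat(ws, thresholds@statistic)
    up <- !is.na(vals) & vals > thresholds@upperValue
    if (!is.na(thresholds@lowerValue))
        up <- up | (!is.na(vals) & vals < thresholds@lowerValue)
    up
}
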