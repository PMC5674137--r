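#' End-to-end QTL-seq analysis of two pooled bulks
#'
#' Runs the full pipeline on a set of pooled variants: quality filters,
#' sliding-window statistics, empirical quantile thresholds on the chosen
#' window statistic, merging of threshold-exceeding windows into candidate
#' intervals, and sparse-interval filtering. With `statistic = "abs_delta"`
#' (the default, robust to heterozygous parents) only an upper tail is
#' thresholded; with `"delta"` the tail mass is split between an upper and a
#' lower threshold, since the sign of the window Delta is informative only
#' when the reference is a parental haplotype.
#'
#' The run is deterministic: identical inputs and parameters give byte
#' identical outputs.
#'
#' @param variants a [PooledVariants] object (e.g. from [readVariants()] or
#'   [simVariants()]).
#' @param seqlengths named scaffold lengths; defaults to the variants'
#'   seqlengths when set.
#' @param statistic `"abs_delta"` (default) or `"delta"`.
#' @param filterPolicy a [FilterPolicy].
#' @param windowSize,step sliding-window geometry in bp (defaults 200 kb /
#'   20 kb).
#' @param upperQ total tail mass flagged (default 0.005, the top 0.5%). For
#'   `"delta"` it is split half and half between the two tails unless
#'   `lowerQ` is given explicitly.
#' @param lowerQ lower tail mass for `"delta"`; ignored for `"abs_delta"`.
#' @param sparsity a [SparsityPolicy].
#' @param minSnpsPerWindow see [windowStatistics()].
#' @param outDir optional directory; when given, window and interval tables
#'   (TSV + BED), a JSON summary and a parameter log are written there.
#' @param prefix file name stem for `outDir` outputs.
#' @return a list with elements `variants` (kept), `droppedReasons`
#'   (table), `windows` ([WindowStats-class]), `thresholds`
#'   ([ThresholdSet-class]), `flags`, `intervalsRaw`, `intervals` (sparse
#'   filtered `GRanges`), `droppedIntervals`, `params` and `summary` (a
#'   list: variant and window counts, realized thresholds, and raw/filtered
#'   total candidate lengths in bp and Mb).
#' @examples
#' sim <- simulateCross(CrossSimConfig(nScaffolds = 2L, scaffoldLength = 5e5,
#'                                     qtlPosition = 2.5e5, nOffspring = 60L,
#'                                     nOffspringPerPool = c(12L, 12L),
#'                                     seed = 11L))
#' res <- runQtlseq(simVariants(sim), sparsity = SparsityPolicy(minSnps = 3))
#' res$summary$totalFilteredMb
#' @seealso [powerExperiment()], [plotWindowStats()]
#' @export
runQtlseq <- function(variants, seqlengths = NULL,
                      statistic = c("abs_delta", "delta"),
                      filterPolicy = FilterPolicy(),
                      windowSize = 200000L, step = 20000L,
                      upperQ = 0.005, lowerQ = NULL,
                      sparsity = SparsityPolicy(),
                      minSnpsPerWindow = 1L,
                      outDir = NULL, prefix = "qtlseq") {
    statistic <- match.arg(statistic)
    stopifnot(is(variants, "PooledVariants"))
    if (length(variants) == 0L)
        stop("empty input: no variant records to analyse")
    if (is.null(seqlengths)) {
        seqlengths <- seqlengths(variantRanges(variants))
        if (!length(seqlengths) || anyNA(seqlengths))
            stop("scaffold lengths unavailable; pass 'seqlengths'")
    }
    filt <- applyFilters(variants, filterPolicy)
    if (length(filt$kept) == 0L)
        stop("empty input: all ", length(variants),
             " variants removed by the quality filters")
    grid <- makeWindowGrid(seqlengths, windowSize, step)
    ws <- windowStatistics(filt$kept, grid,
                           minSnpsPerWindow = minSnpsPerWindow)
    if (statistic == "delta") {
        uq <- if (is.null(lowerQ)) upperQ / 2 else upperQ
        lq <- if (is.null(lowerQ)) upperQ / 2 else lowerQ
        thr <- quantileThresholds(ws, "delta", upperQ = uq, lowerQ = lq)
    } else {
        thr <- quantileThresholds(ws, "abs_delta", upperQ = upperQ)
    }
    flags <- flagWindows(ws, thr)
    raw <- callIntervals(ws, flags = flags, variants = filt$kept)
    sp <- filterSparse(raw, filt$kept, sparsity)

    params <- list(statistic = statistic,
                   poolNames = poolNames(variants),
                   minIndex = filterPolicy@minIndex,
                   minDepth = filterPolicy@minDepth,
                   dropIfMissingInOnePool = filterPolicy@dropIfMissingInOnePool,
                   indexRule = filterPolicy@indexRule,
                   windowSize = as.integer(windowSize),
                   step = as.integer(step),
                   upperQ = thr@upperQ, lowerQ = thr@lowerQ,
                   sparsityMinSnps = sparsity@minSnps,
                   sparsityMaxMedianGap = sparsity@maxMedianGap,
                   minSnpsPerWindow = as.integer(minSnpsPerWindow))
    summary <- list(
        nVariantsIn = length(variants),
        nVariantsKept = length(filt$kept),
        nWindows = length(windowRanges(ws)),
        nWindowsFlagged = sum(flags),
        upperThreshold = thr@upperValue,
        lowerThreshold = thr@lowerValue,
        nIntervalsRaw = length(raw),
        nIntervals = length(sp$kept),
        totalRawBp = totalLength(raw, "bp"),
        totalRawMb = totalLength(raw, "Mb"),
        totalFilteredBp = totalLength(sp$kept, "bp"),
        totalFilteredMb = totalLength(sp$kept, "Mb"))
    res <- list(variants = filt$kept,
                droppedReasons = table(filt$reasons),
                windows = ws, thresholds = thr, flags = flags,
                intervalsRaw = raw, intervals = sp$kept,
                droppedIntervals = sp$dropped,
                params = params, summary = summary)
    if (!is.null(outDir)) .writeReportBundle(res, outDir, prefix)
    res
}

#' Write sliding-window statistics as a BED-like TSV
#'
#' Columns: scaffold, 0-based half-open start (`start − 1`), end, nSNPs and
#' the four window means. Internal coordinates stay 1-based inclusive; only
#' the writer converts.
#'
#' @param ws a [WindowStats-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWindowStats <- function(ws, path) {
    w <- windowRanges(ws)
    md <- mcols(w)
    num <- function(v) ifelse(is.na(v), "NA", sprintf("%.6g", v))
    tab <- data.frame(scaffold = as.character(seqnames(w)),
                      start = start(w) - 1L, end = end(w),
                      n_snps = md$nSNPs,
                      mean_index_a = num(md$meanIndexA),
                      mean_index_b = num(md$meanIndexB),
                      mean_delta = num(md$meanDelta),
                      mean_abs_delta = num(md$meanAbsDelta))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.writeReportBundle <- function(res, outDir, prefix) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    pth <- function(ext) file.path(outDir, paste0(prefix, ".", ext))
    ok <- FALSE
    written <- character(0)
    on.exit(if (!ok) unlink(written), add = TRUE)
    wr <- function(f, ext) { p <- pth(ext); written <<- c(written, p); f(p); p }
    wr(function(p) writeWindowStats(res$windows, p), "windows.tsv")
    wr(function(p) writeIntervalsBed(res$intervals, p), "intervals.bed")
    wr(function(p) writeIntervalsTsv(res$intervals, p), "intervals.tsv")
    wr(function(p) jsonlite::write_json(
        list(schema = "absQTLseq-summary-1",
             params = res$params, summary = res$summary,
             droppedVariants = as.list(res$droppedReasons)),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE), "summary.json")
    wr(function(p) writeLines(c(
        paste0("# absQTLseq run, package version ",
               as.character(packageVersion("absQTLseq"))),
        paste0(names(res$params), " = ",
               vapply(res$params, function(v) paste(v, collapse = ","),
                      character(1L)))), p), "params.log")
    ok <- TRUE
    invisible(outDir)
}
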