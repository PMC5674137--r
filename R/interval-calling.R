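#' Merge threshold-exceeding windows into candidate intervals
#'
#' Takes the union, per scaffold, of the spans of flagged windows, merging
#' windows that overlap or abut. Because windows lie on the step grid, the
#' merged interval boundaries land on that grid too (starts ...0001, ends
#' ...0000 for the default 20-kb step). The result is independent of window
#' order; intervals on a scaffold are disjoint and sorted. The number of
#' kept variants inside each interval is attached when `variants` is given.
#'
#' @param ws a [WindowStats-class] object.
#' @param thresholds a [ThresholdSet-class]; used to compute flags when
#'   `flags` is missing.
#' @param flags optional logical vector parallel to the windows, overriding
#'   `thresholds`.
#' @param variants optional [PooledVariants] (the filtered set) used to
#'   annotate each interval with its `nSNPs`.
#' @return a `GRanges` of candidate intervals (possibly empty), with an
#'   `nSNPs` metadata column when `variants` was supplied.
#' @examples
#' pv <- PooledVariants("s1", seq(1000L, 299000L, 1000L), "A", "G",
#'                      adRefA = 10L, adAltA = 10L, adRefB = 16L, adAltB = 4L)
#' ws <- windowStatistics(pv, makeWindowGrid(c(s1 = 300000)))
#' callIntervals(ws, flags = rep(c(TRUE, FALSE, TRUE), c(2, 10, 3)))
#' @seealso [filterSparse()], [intervalLength()]
#' @export
callIntervals <- function(ws, thresholds = NULL, flags = NULL,
                          variants = NULL) {
    stopifnot(is(ws, "WindowStats"))
    w <- windowRanges(ws)
    if (is.null(flags)) {
        if (is.null(thresholds))
            stop("supply either 'thresholds' or 'flags'")
        flags <- flagWindows(ws, thresholds)
    }
    if (length(flags) != length(w))
        stop("'flags' must be parallel to the windows")
    out <- reduce(sort(w[which(flags)]), min.gapwidth = 1L,
                  ignore.strand = TRUE)
    mcols(out) <- NULL
    if (!is.null(variants) && length(out))
        out$nSNPs <- countOverlaps(out, variantRanges(variants),
                                   ignore.strand = TRUE)
    out
}

#' Drop candidate intervals supported by few, widely separated SNPs
#'
#' Applies a [SparsityPolicy]: an interval is dropped when it contains fewer
#' than `minSnps` variants, or when the median gap between consecutive
#' variant positions inside it exceeds `maxMedianGap` bp (gaps are defined
#' only for intervals with at least two variants). The operation is
#' idempotent.
#'
#' @param intervals a `GRanges` of candidate intervals.
#' @param variants the [PooledVariants] (filtered set) whose positions
#'   support the intervals.
#' @param policy a [SparsityPolicy].
#' @return a list: `kept` and `dropped` (`GRanges`, with `nSNPs` and
#'   `medianGap` columns) and `reasons`, a factor parallel to `dropped` with
#'   levels `few_snps` and `wide_gaps`.
#' @examples
#' iv <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 200000))
#' pv <- PooledVariants("s1", c(10000L, 160000L), "A", "G",
#'                      adRefA = 10L, adAltA = 10L, adRefB = 10L, adAltB = 10L)
#' filterSparse(iv, pv)$reasons    # few_snps
#' @export
filterSparse <- function(intervals, variants, policy = SparsityPolicy()) {
    stopifnot(is(policy, "SparsityPolicy"))
    if (!length(intervals))
        return(list(kept = intervals, dropped = intervals,
                    reasons = factor(character(),
                                     levels = c("few_snps", "wide_gaps"))))
    pos <- variantRanges(variants)
    hits <- findOverlaps(intervals, pos, ignore.strand = TRUE)
    n <- length(intervals)
    nS <- tabulate(queryHits(hits), nbins = n)
    medGap <- rep(NA_real_, n)
    for (i in unique(queryHits(hits))) {
        p <- sort(start(pos)[subjectHits(hits)[queryHits(hits) == i]])
        if (length(p) >= 2L) medGap[i] <- median(diff(p))
    }
    reason <- rep(NA_character_, n)
    reason[!is.na(medGap) & medGap > policy@maxMedianGap] <- "wide_gaps"
    reason[nS < policy@minSnps] <- "few_snps"
    intervals$nSNPs <- nS
    intervals$medianGap <- medGap
    drop <- !is.na(reason)
    list(kept = intervals[!drop], dropped = intervals[drop],
         reasons = factor(reason[drop], levels = c("few_snps", "wide_gaps")))
}

#' Interval lengths in bp, kb or Mb under both printed conventions
#'
#' Two length conventions coexist in candidate-region reporting and both are
#' supported explicitly: `"inclusive"` counts bases, `end − start + 1`, the
#' natural length of window-grid regions whose 1-based boundaries land on
#' ...0001/...0000; `"difference"` is the coordinate difference
#' `end − start`, the span between two marker positions. Values are exact;
#' round for display (reports print kb to one decimal).
#'
#' @param x a `GRanges`, or a two-column matrix/data.frame of (start, end).
#' @param unit `"bp"`, `"kb"` or `"Mb"`.
#' @param mode `"inclusive"` (default) or `"difference"`.
#' @return numeric vector of lengths.
#' @examples
#' iv <- GenomicRanges::GRanges("s", IRanges::IRanges(3800001, 3880000))
#' intervalLength(iv, "kb")                        # 80
#' mk <- GenomicRanges::GRanges("s", IRanges::IRanges(3639340, 4167794))
#' round(intervalLength(mk, "kb", "difference"), 1)  # 528.5
#' @export
intervalLength <- function(x, unit = c("bp", "kb", "Mb"),
                           mode = c("inclusive", "difference")) {
    unit <- match.arg(unit); mode <- match.arg(mode)
    if (is(x, "GRanges")) {
        s <- start(x); e <- end(x)
    } else {
        x <- as.matrix(x)
        s <- as.numeric(x[, 1L]); e <- as.numeric(x[, 2L])
    }
    if (any(e < s)) stop("interval end before start")
    bp <- if (mode == "inclusive") e - s + 1 else e - s
    bp / switch(unit, bp = 1, kb = 1e3, Mb = 1e6)
}

#' Total length of a set of candidate intervals
#'
#' Overlapping or duplicated input intervals are merged (per scaffold)
#' before summing, so the total never double-counts bases.
#'
#' @inheritParams intervalLength
#' @param x a `GRanges`.
#' @return a single numeric total.
#' @examples
#' iv <- GenomicRanges::GRanges(c("s1", "s1"),
#'                              IRanges::IRanges(c(1, 1), c(200000, 200000)))
#' totalLength(iv, "Mb")   # 0.2, not 0.4
#' @export
totalLength <- function(x, unit = c("bp", "kb", "Mb"),
                        mode = c("inclusive", "difference")) {
    if (!length(x)) return(0)
    merged <- reduce(sort(x), min.gapwidth = 1L, ignore.strand = TRUE)
    sum(intervalLength(merged, unit, mode))
}

#' Genetic distance between two map positions
#'
#' @param posA,posB positions in centimorgans (vectorized).
#' @return `|posA − posB|` in cM.
#' @examples
#' mapDistance(6.1, 8.6)   # 2.5
#' @export
mapDistance <- function(posA, posB) abs(posA - posB)

#' Read a linkage-map marker table
#'
#' Tab-separated table with columns `locus`, `scaffold`, `scaffold_position`
#' and `map_position_cM`; dashes or blanks denote unplaced markers and
#' become `NA`.
#'
#' @param path TSV file.
#' @return a `data.frame` with numeric positions.
#' @export
readLinkageMap <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus", "scaffold", "scaffold_position", "map_position_cM")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("linkage map lacks column(s): ", paste(miss, collapse = ", "))
    toNum <- function(v) suppressWarnings(
        as.numeric(gsub("[ , ]", "", ifelse(v %in% c("-", "—", ""),
                                                 NA, v))))
    tab$scaffold_position <- toNum(tab$scaffold_position)
    tab$map_position_cM <- toNum(tab$map_position_cM)
    tab
}

#' Write candidate intervals as BED and as a 1-based report table
#'
#' `writeIntervalsBed` writes 0-based half-open BED (start − 1, end);
#' `writeIntervalsTsv` writes the human-readable layout used in candidate
#' region reports: scaffold, 1-based inclusive start and end, and the region
#' length in kb (one decimal), with a Total row in Mb.
#'
#' @param intervals a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @rdname writeIntervals
#' @export
writeIntervalsBed <- function(intervals, path) {
    tab <- data.frame(as.character(seqnames(intervals)),
                      format(start(intervals) - 1L, scientific = FALSE, trim = TRUE),
                      format(end(intervals), scientific = FALSE, trim = TRUE))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeIntervals
#' @export
writeIntervalsTsv <- function(intervals, path) {
    kb <- intervalLength(intervals, "kb", "inclusive")
    tab <- data.frame(scaffold = as.character(seqnames(intervals)),
                      start = start(intervals), end = end(intervals),
                      region_length_kb = sprintf("%.1f", kb))
    tot <- sprintf("%.2f Mb", totalLength(intervals, "Mb", "inclusive"))
    con <- file(path, "w")
    on.exit(close(con))
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste("Total", "", "", tot, sep = "\t"), con)
    invisible(path)
}
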