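#' Per-scaffold tracks of SNP-index, Delta and |Delta| window means
#'
#' Draws the four sliding-window tracks (SNP-index of each pool, signed
#' Delta(SNP-index), |Delta(SNP-index)|) along each scaffold, with the
#' realized quantile threshold line(s) overlaid on the track they apply to.
#'
#' @param ws a [WindowStats-class] object.
#' @param thresholds optional [ThresholdSet-class]; draws dashed threshold
#'   lines on the matching track.
#' @param scaffolds optional character vector restricting the scaffolds
#'   shown.
#' @return a `ggplot` object (facets: track rows x scaffold columns).
#' @examples
#' pv <- PooledVariants("s1", seq(1000L, 399000L, 2000L), "A", "G",
#'                      adRefA = 10L, adAltA = 10L, adRefB = 15L, adAltB = 5L)
#' ws <- windowStatistics(pv, makeWindowGrid(c(s1 = 400000)))
#' p <- plotWindowStats(ws)
#' @export
plotWindowStats <- function(ws, thresholds = NULL, scaffolds = NULL) {
    w <- windowRanges(ws)
    if (!is.null(scaffolds))
        w <- w[as.character(seqnames(w)) %in% scaffolds]
    mid <- (start(w) + end(w)) / 2 / 1e6
    pools <- poolNames(ws)
    long <- rbind(
        data.frame(scaffold = as.character(seqnames(w)), mb = mid,
                   track = paste0("SNP-index ", pools[1L]),
                   value = w$meanIndexA),
        data.frame(scaffold = as.character(seqnames(w)), mb = mid,
                   track = paste0("SNP-index ", pools[2L]),
                   value = w$meanIndexB),
        data.frame(scaffold = as.character(seqnames(w)), mb = mid,
                   track = "Delta(SNP-index)", value = w$meanDelta),
        data.frame(scaffold = as.character(seqnames(w)), mb = mid,
                   track = "|Delta(SNP-index)|", value = w$meanAbsDelta))
    long$track <- factor(long$track, levels = unique(long$track))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$value)) +
        ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
        ggplot2::facet_grid(track ~ scaffold, scales = "free") +
        ggplot2::labs(x = "position (Mb)", y = NULL) +
        ggplot2::theme_bw(base_size = 9)
    if (!is.null(thresholds)) {
        trk <- if (thresholds@statistic == "abs_delta")
            "|Delta(SNP-index)|" else "Delta(SNP-index)"
        hl <- data.frame(track = factor(trk, levels = levels(long$track)),
                         y = c(thresholds@upperValue, thresholds@lowerValue))
        hl <- hl[!is.na(hl$y), , drop = FALSE]
        p <- p + ggplot2::geom_hline(data = hl,
                                     ggplot2::aes(yintercept = .data$y),
                                     linetype = 2, colour = "red",
                                     linewidth = 0.3)
    }
    p
}
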