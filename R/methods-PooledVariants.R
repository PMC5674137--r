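#' Per-pool SNP-index of pooled variants
#'
#' The SNP-index of a pool at a site is the fraction of its reads carrying
#' the non-reference allele: alt/(ref+alt), `NA` at zero depth.
#'
#' @param x a [PooledVariants] object.
#' @param pool `"A"` or `"B"`, or one of the pool names stored in `x`.
#' @return numeric vector in \[0,1\] with `NA` for zero-depth sites.
#' @examples
#' pv <- PooledVariants("s1", 1:2, "A", "G", adRefA = c(0L, 5L),
#'                      adAltA = c(20L, 5L), adRefB = c(10L, 0L),
#'                      adAltB = c(10L, 0L))
#' snpIndex(pv, "A")
#' @rdname snpIndex
#' @export
setMethod("snpIndex", "PooledVariants", function(x, pool = c("A", "B")) {
    if (pool[1L] %in% x@poolNames)
        pool <- c("A", "B")[match(pool[1L], x@poolNames)]
    pool <- match.arg(pool)
    mcols(x@ranges)[[paste0("index", pool)]]
})

#' Per-variant Delta(SNP-index) and |Delta(SNP-index)|
#'
#' `deltaIndex` returns SNP-index(pool A) − SNP-index(pool B) per site, in
#' \[−1,1\]; `absDeltaIndex` its absolute value. Missing indices propagate.
#' The sign convention (which bulk is pool A) is the `poolNames` orientation
#' of `x`. The sign-free statistic is robust to the reference genome
#' switching haplotype state along a scaffold, which randomly flips the sign
#' of the per-site Delta in heterozygous material ("pseudoexchange").
#'
#' @param x a [PooledVariants] object.
#' @return numeric vector, `NA` where either pool's index is missing.
#' @examples
#' pv <- PooledVariants("s1", 1L, "A", "G", adRefA = 0L, adAltA = 20L,
#'                      adRefB = 20L, adAltB = 0L)
#' deltaIndex(pv)      # +1
#' absDeltaIndex(pv)   # 1
#' @rdname deltaIndex
#' @export
setMethod("deltaIndex", "PooledVariants", function(x)
    mcols(x@ranges)$indexA - mcols(x@ranges)$indexB)

#' @rdname deltaIndex
#' @export
setMethod("absDeltaIndex", "PooledVariants", function(x)
    abs(deltaIndex(x)))

#' Pool names and orientation
#'
#' Names of the two bulks, in (A, B) order; the sign of Delta(SNP-index) is
#' index(A) − index(B).
#'
#' @param x a [PooledVariants], [WindowStats-class] or [CrossSim-class] object.
#' @return character(2).
#' @rdname poolNames
#' @export
setMethod("poolNames", "PooledVariants", function(x) x@poolNames)

#' Variant positions as a GRanges
#'
#' Width-1 ranges at each variant position, with the ref/alt alleles, the
#' four per-pool allele depths and the two SNP-indices as metadata columns.
#'
#' @param x a [PooledVariants] object.
#' @return a `GRanges`.
#' @rdname variantRanges
#' @export
setMethod("variantRanges", "PooledVariants", function(x) x@ranges)

#' @describeIn PooledVariants number of variant records.
#' @param x a `PooledVariants` object.
#' @export
setMethod("length", "PooledVariants", function(x) length(x@ranges))

#' @describeIn PooledVariants subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PooledVariants", function(x, i, j, ..., drop = TRUE) {
    initialize(x, ranges = x@ranges[i], poolNames = x@poolNames)
})

#' Coerce pooled variants to a data.frame
#'
#' @param x a [PooledVariants] object.
#' @param row.names,optional,... passed on conventions; ignored.
#' @return a `data.frame` with scaffold, position, alleles, depths, indices.
#' @export
#' @method as.data.frame PooledVariants
as.data.frame.PooledVariants <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    gr <- x@ranges
    data.frame(scaffold = as.character(seqnames(gr)),
               position = start(gr),
               as.data.frame(mcols(gr)),
               stringsAsFactors = FALSE)
}

setMethod("show", "PooledVariants", function(object) {
    cat("PooledVariants with", length(object), "sites on",
        length(unique(as.character(seqnames(object@ranges)))), "scaffold(s)\n")
    cat("  pools (A, B):", paste(object@poolNames, collapse = ", "), "\n")
    if (length(object)) {
        d <- deltaIndex(object)
        cat(sprintf("  mean |Delta(SNP-index)|: %.3f (%d sites with both indices)\n",
                    mean(abs(d), na.rm = TRUE), sum(!is.na(d))))
    }
    invisible(NULL)
})

setMethod("show", "WindowStats", function(object) {
    cat("WindowStats:", length(object@windows), "windows (",
        object@windowSize, "bp /", object@step, "bp step )\n")
    cat("  pools (A, B):", paste(object@poolNames, collapse = ", "), "\n")
    nz <- sum(mcols(object@windows)$nSNPs > 0L)
    cat("  windows with >=1 SNP:", nz, "\n")
    invisible(NULL)
})

#' Window ranges of a WindowStats object
#'
#' The sliding-window grid as a `GRanges` with the summary statistics
#' (`nSNPs`, `meanIndexA`, `meanIndexB`, `meanDelta`, `meanAbsDelta`) as
#' metadata columns.
#'
#' @param x a [WindowStats-class] object.
#' @return a `GRanges`.
#' @rdname windowRanges
#' @export
setMethod("windowRanges", "WindowStats", function(x) x@windows)

#' @rdname poolNames
#' @export
setMethod("poolNames", "WindowStats", function(x) x@poolNames)

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet on", object@statistic, "windows\n")
    cat(sprintf("  upper: q=%.4g -> %s\n", object@upperQ,
                formatC(object@upperValue, digits = 4)))
    if (!is.na(object@lowerQ))
        cat(sprintf("  lower: q=%.4g -> %s\n", object@lowerQ,
                    formatC(object@lowerValue, digits = 4)))
    invisible(NULL)
})

setMethod("show", "CrossSimConfig", function(object) {
    cat("CrossSimConfig:", object@nScaffolds, "x",
        format(object@scaffoldLength, big.mark = ","), "bp;",
        object@crossType, "cross;", object@referenceMode, "reference\n")
    cat(sprintf("  QTL at scaffold %d : %s; pools %d + %d of %d offspring; depth %gx\n",
                object@qtlScaffold, format(object@qtlPosition, big.mark = ","),
                object@nOffspringPerPool[1L], object@nOffspringPerPool[2L],
                object@nOffspring, object@meanDepth))
    invisible(NULL)
})

setMethod("show", "CrossSim", function(object) {
    cat("CrossSim (seed", object@truth$seed, ")\n")
    show(object@config)
    show(object@variants)
    invisible(NULL)
})

#' Accessors for simulated-cross bundles
#'
#' `simVariants` returns the simulated [PooledVariants]; `simTruth` the
#' ground-truth list (`qtlScaffold`, `qtlPosition`, `phenotype`, `poolA`,
#' `poolB`, `breakpoints`, `seed`); `simConfig` the [CrossSimConfig];
#' `simSeqlengths` the named scaffold lengths.
#'
#' @param x a [CrossSim-class] object.
#' @return see description.
#' @rdname simAccessors
#' @export
simVariants <- function(x) x@variants

#' @rdname simAccessors
#' @export
simTruth <- function(x) x@truth

#' @rdname simAccessors
#' @export
simConfig <- function(x) x@config

#' @rdname simAccessors
#' @export
simSeqlengths <- function(x) x@seqlengths
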