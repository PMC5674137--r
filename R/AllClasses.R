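.FilterPolicy <- setClass("FilterPolicy",
    representation(minIndex = "numeric", minDepth = "integer",
                   dropIfMissingInOnePool = "logical", indexRule = "character"),
    prototype(minIndex = 0.3, minDepth = 7L, dropIfMissingInOnePool = TRUE,
              indexRule = "both_pools_below"))

setValidity("FilterPolicy", function(object) {
    msg <- NULL
    if (length(object@minIndex) != 1L || is.na(object@minIndex) ||
        object@minIndex < 0 || object@minIndex > 1)
        msg <- c(msg, "'minIndex' must be a single value in [0,1]")
    if (length(object@minDepth) != 1L || is.na(object@minDepth) || object@minDepth < 0L)
        msg <- c(msg, "'minDepth' must be a single non-negative integer")
    if (length(object@indexRule) != 1L ||
        !object@indexRule %in% c("both_pools_below", "either_pool_below"))
        msg <- c(msg, "'indexRule' must be 'both_pools_below' or 'either_pool_below'")
    if (is.null(msg)) TRUE else msg
})

#' Quality-filter policy for pooled variant records
#'
#' Encodes the low-quality SNP exclusion rules applied before sliding-window
#' analysis: a minimum per-pool SNP-index, a minimum per-pool read depth, and
#' removal of sites lacking an SNP-index in one of the two pools. The index
#' rule decides whether a site is dropped when its SNP-index is below
#' `minIndex` in both pools (the classical choice: the site is uninformative
#' in both bulks) or in either pool.
#'
#' @param minIndex numeric in \[0,1\]; SNP-index cutoff (default 0.3).
#' @param minDepth non-negative integer; per-pool total read-depth cutoff
#'   (default 7). A site is dropped when either pool is below it.
#' @param dropIfMissingInOnePool logical; drop sites whose SNP-index is
#'   missing (zero depth) in at least one pool (default TRUE).
#' @param indexRule `"both_pools_below"` (default) or `"either_pool_below"`.
#'
#' @return A `FilterPolicy` object.
#' @examples
#' FilterPolicy()
#' FilterPolicy(minIndex = 0.25, indexRule = "either_pool_below")
#' @seealso [applyFilters()]
#' @aliases FilterPolicy-class
#' @export
FilterPolicy <- function(minIndex = 0.3, minDepth = 7L,
                         dropIfMissingInOnePool = TRUE,
                         indexRule = c("both_pools_below", "either_pool_below")) {
    indexRule <- match.arg(indexRule)
    .FilterPolicy(minIndex = as.numeric(minIndex),
                  minDepth = as.integer(minDepth),
                  dropIfMissingInOnePool = as.logical(dropIfMissingInOnePool),
                  indexRule = indexRule)
}

.pv_mcols <- c("ref", "alt", "adRefA", "adAltA", "adRefB", "adAltB",
               "indexA", "indexB")

.PooledVariants <- setClass("PooledVariants",
    representation(ranges = "GRanges", poolNames = "character"))

setValidity("PooledVariants", function(object) {
    msg <- NULL
    if (length(object@poolNames) != 2L || anyNA(object@poolNames))
        msg <- c(msg, "'poolNames' must be two sample names")
    miss <- setdiff(.pv_mcols, colnames(mcols(object@ranges)))
    if (length(miss))
        msg <- c(msg, paste0("missing variant columns: ",
                             paste(miss, collapse = ", ")))
    if (length(object@ranges) && !length(miss)) {
        if (any(start(object@ranges) < 1L))
            msg <- c(msg, "positions must be >= 1")
        for (nm in c("indexA", "indexB")) {
            v <- mcols(object@ranges)[[nm]]
            if (any(!is.na(v) & (v < 0 | v > 1)))
                msg <- c(msg, paste0("'", nm, "' outside [0,1]"))
        }
        dp <- as.matrix(mcols(object@ranges)[, c("adRefA", "adAltA",
                                                 "adRefB", "adAltB")])
        if (any(!is.na(dp) & dp < 0))
            msg <- c(msg, "read depths must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Pooled biallelic variants with per-pool SNP-indices
#'
#' One record per biallelic site carrying ref/alt allele read depths for two
#' phenotype pools (A and B) and the derived per-pool SNP-indices. The
#' SNP-index of a pool is alt depth / (ref depth + alt depth) — the fraction
#' of reads differing from the reference allele: 1 when all reads carry the
#' alternate allele, 0 when all match the reference, `NA` when the pool has
#' zero depth at the site. Records are kept sorted by (scaffold, position).
#'
#' @param scaffold character vector of scaffold/chromosome identifiers.
#' @param position integer vector of 1-based positions.
#' @param ref,alt reference and alternate allele sequences (InDels — unequal
#'   lengths — are accepted and flow through the same index arithmetic).
#' @param adRefA,adAltA,adRefB,adAltB non-negative read depths per pool;
#'   `NA` depths give a missing SNP-index for that pool.
#' @param poolNames character(2): names of pool A and pool B, in that order.
#'   Pool orientation (which bulk is A) fixes the sign of Delta(SNP-index)
#'   and is recorded in all downstream output.
#' @param seqlengths optional named vector of scaffold lengths; its name
#'   order defines the scaffold sort order (alphabetical otherwise).
#'
#' @return A `PooledVariants` object.
#' @examples
#' pv <- PooledVariants("s1", 100L, "A", "G",
#'                      adRefA = 0L, adAltA = 20L, adRefB = 10L, adAltB = 10L,
#'                      poolNames = c("red", "green"))
#' snpIndex(pv, "A")   # 1.0
#' deltaIndex(pv)      # 0.5
#' @seealso [readVariants()], [applyFilters()], [windowStatistics()]
#' @aliases PooledVariants-class
#' @export
PooledVariants <- function(scaffold, position, ref, alt,
                           adRefA, adAltA, adRefB, adAltB,
                           poolNames = c("poolA", "poolB"),
                           seqlengths = NULL) {
    n <- length(position)
    lvls <- if (!is.null(seqlengths)) names(seqlengths) else
        sort(unique(as.character(scaffold)))
    gr <- GRanges(factor(as.character(scaffold), levels = lvls),
                  IRanges(as.integer(position), width = 1L))
    if (!is.null(seqlengths))
        seqlengths(gr) <- as.integer(seqlengths)
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        adRefA = as.integer(adRefA), adAltA = as.integer(adAltA),
        adRefB = as.integer(adRefB), adAltB = as.integer(adAltB))
    gr$indexA <- computeSnpIndex(gr$adAltA, gr$adRefA)
    gr$indexB <- computeSnpIndex(gr$adAltB, gr$adRefB)
    gr <- sort(gr)
    .PooledVariants(ranges = gr, poolNames = as.character(poolNames))
}

.ws_mcols <- c("nSNPs", "meanIndexA", "meanIndexB", "meanDelta", "meanAbsDelta")

.WindowStats <- setClass("WindowStats",
    representation(windows = "GRanges", windowSize = "integer",
                   step = "integer", poolNames = "character"))

setValidity("WindowStats", function(object) {
    msg <- NULL
    miss <- setdiff(.ws_mcols, colnames(mcols(object@windows)))
    if (length(miss))
        msg <- c(msg, paste0("missing window columns: ",
                             paste(miss, collapse = ", ")))
    if (length(object@windowSize) != 1L || object@windowSize < 1L ||
        length(object@step) != 1L || object@step < 1L)
        msg <- c(msg, "'windowSize' and 'step' must be positive scalars")
    if (length(object@windows) && !length(miss)) {
        w <- object@windows
        if (any(width(w) > object@windowSize))
            msg <- c(msg, "window wider than 'windowSize'")
        if (any((start(w) - 1L) %% object@step != 0L))
            msg <- c(msg, "window starts must lie on the grid 1 + k*step")
        md <- mcols(w)
        both <- !is.na(md$meanDelta) & !is.na(md$meanAbsDelta)
        if (any(both & md$meanAbsDelta < abs(md$meanDelta) - 1e-9))
            msg <- c(msg, "mean |Delta| below |mean Delta|: impossible means")
        allna <- is.na(md$meanIndexA) & is.na(md$meanIndexB) &
            is.na(md$meanDelta) & is.na(md$meanAbsDelta)
        if (any(md$nSNPs == 0L & !allna))
            msg <- c(msg, "empty windows must have all statistics missing")
    }
    if (is.null(msg)) TRUE else msg
})

#' @name WindowStats-class
#' @title Sliding-window summaries of SNP-index statistics
#'
#' @description Fixed-width windows advanced by a fixed step along each
#' scaffold, each holding the number of contributing SNPs and the arithmetic
#' means of the per-pool SNP-indices, the signed Delta(SNP-index) and
#' |Delta(SNP-index)| over the SNPs it contains. Windows at scaffold ends are
#' truncated, never discarded. Produced by [windowStatistics()].
#'
#' @seealso [makeWindowGrid()], [quantileThresholds()], [callIntervals()]
#' @aliases WindowStats
#' @exportClass WindowStats
NULL

.ThresholdSet <- setClass("ThresholdSet",
    representation(statistic = "character", upperQ = "numeric",
                   lowerQ = "numeric", upperValue = "numeric",
                   lowerValue = "numeric"))

setValidity("ThresholdSet", function(object) {
    msg <- NULL
    if (!object@statistic %in% c("delta", "abs_delta"))
        msg <- c(msg, "'statistic' must be 'delta' or 'abs_delta'")
    if (!is.na(object@upperQ) && (object@upperQ <= 0 || object@upperQ >= 1))
        msg <- c(msg, "'upperQ' must be in (0,1)")
    if (!is.na(object@lowerQ) && (object@lowerQ <= 0 || object@lowerQ >= 1))
        msg <- c(msg, "'lowerQ' must be in (0,1)")
    if (!is.na(object@upperValue) && !is.na(object@lowerValue) &&
        object@upperValue < object@lowerValue)
        msg <- c(msg, "'upperValue' must be >= 'lowerValue'")
    if (is.null(msg)) TRUE else msg
})

#' @name ThresholdSet-class
#' @title Quantile thresholds realized on a window-statistic distribution
#'
#' @description Stores the quantile levels and the threshold values they
#' realize on the empirical distribution of non-missing window statistics:
#' an upper tail for |Delta(SNP-index)| (e.g. the top 0.5%) or upper plus
#' lower tails for the signed Delta(SNP-index) (e.g. top and lowermost
#' 0.25%). Realized thresholds are data-dependent outputs, not constants.
#'
#' @seealso [quantileThresholds()], [flagWindows()]
#' @aliases ThresholdSet
#' @exportClass ThresholdSet
NULL

.SparsityPolicy <- setClass("SparsityPolicy",
    representation(minSnps = "integer", maxMedianGap = "numeric"),
    prototype(minSnps = 10L, maxMedianGap = 20000))

setValidity("SparsityPolicy", function(object) {
    msg <- NULL
    if (length(object@minSnps) != 1L || is.na(object@minSnps) ||
        object@minSnps < 0L)
        msg <- c(msg, "'minSnps' must be a single non-negative integer")
    if (length(object@maxMedianGap) != 1L || is.na(object@maxMedianGap) ||
        object@maxMedianGap < 1)
        msg <- c(msg, "'maxMedianGap' must be >= 1 bp")
    if (is.null(msg)) TRUE else msg
})

#' Sparse-interval filter policy
#'
#' Candidate intervals supported by only a few, widely separated SNPs are
#' discarded: an interval is dropped when it contains fewer than `minSnps`
#' contributing SNPs, or when the median gap between consecutive SNPs inside
#' it exceeds `maxMedianGap` bp.
#'
#' @param minSnps non-negative integer (default 10).
#' @param maxMedianGap positive number of bp (default 20000, one window step).
#' @return A `SparsityPolicy` object.
#' @examples
#' SparsityPolicy(minSnps = 5, maxMedianGap = 5e4)
#' @seealso [filterSparse()]
#' @aliases SparsityPolicy-class
#' @export
SparsityPolicy <- function(minSnps = 10L, maxMedianGap = 20000) {
    .SparsityPolicy(minSnps = as.integer(minSnps),
                    maxMedianGap = as.numeric(maxMedianGap))
}

.CrossSimConfig <- setClass("CrossSimConfig",
    representation(nScaffolds = "integer", scaffoldLength = "numeric",
                   snpDensity = "numeric", qtlScaffold = "integer",
                   qtlPosition = "numeric", parentHeterozygosity = "numeric",
                   recombinationRate = "numeric", nOffspring = "integer",
                   nOffspringPerPool = "integer", meanDepth = "numeric",
                   sequencingError = "numeric", referenceMode = "character",
                   mosaicSwitchRate = "numeric", penetrance = "numeric",
                   crossType = "character", seed = "integer"))

setValidity("CrossSimConfig", function(object) {
    msg <- NULL
    chk01 <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            paste0("'", nm, "' must be a single value in [0,1]")
    }
    msg <- c(msg,
             chk01(object@parentHeterozygosity, "parentHeterozygosity"),
             chk01(object@sequencingError, "sequencingError"),
             chk01(object@penetrance, "penetrance"))
    if (object@nScaffolds < 1L) msg <- c(msg, "'nScaffolds' must be >= 1")
    if (object@scaffoldLength < 1) msg <- c(msg, "'scaffoldLength' must be >= 1 bp")
    if (object@snpDensity < 0) msg <- c(msg, "'snpDensity' must be >= 0")
    if (object@qtlScaffold < 1L || object@qtlScaffold > object@nScaffolds)
        msg <- c(msg, "'qtlScaffold' out of range")
    if (object@qtlPosition < 1 || object@qtlPosition > object@scaffoldLength)
        msg <- c(msg, "'qtlPosition' must lie on the scaffold")
    if (object@recombinationRate < 0)
        msg <- c(msg, "'recombinationRate' must be >= 0")
    if (length(object@nOffspringPerPool) != 2L ||
        any(object@nOffspringPerPool < 1L))
        msg <- c(msg, "'nOffspringPerPool' must be two positive pool sizes")
    if (object@nOffspring < sum(object@nOffspringPerPool))
        msg <- c(msg, "'nOffspring' smaller than the two pools combined")
    if (object@meanDepth <= 0) msg <- c(msg, "'meanDepth' must be positive")
    if (object@mosaicSwitchRate < 0)
        msg <- c(msg, "'mosaicSwitchRate' must be >= 0")
    if (!object@referenceMode %in% c("parental", "mosaic"))
        msg <- c(msg, "'referenceMode' must be 'parental' or 'mosaic'")
    if (!object@crossType %in% c("RrXrr", "RrXRr"))
        msg <- c(msg, "'crossType' must be 'RrXrr' or 'RrXRr'")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of a simulated pooled-sequencing F1 cross
#'
#' Full parameterization of the synthetic biparental cross between two
#' heterozygous parents, the trait locus, the phenotype bulks and the pooled
#' sequencing step, including the mosaic-reference model that reproduces the
#' "pseudoexchange" sign-flips of Delta(SNP-index).
#'
#' The defaults describe the study conditions the package's power analyses
#' use throughout: a toy genome of 5 scaffolds of 2 Mb, 2 segregating sites
#' per kb, highly heterozygous parents (40% of sites heterozygous per
#' parent), 4 cM/Mb recombination, bulks of 28 carrier and 27 non-carrier
#' offspring out of 100 phenotyped F1s, 20x pooled depth, and a mosaic
#' reference switching haplotype state 5 times per Mb.
#'
#' @param nScaffolds number of scaffolds in the toy genome.
#' @param scaffoldLength length of each scaffold in bp.
#' @param snpDensity expected segregating sites per bp.
#' @param qtlScaffold,qtlPosition location of the single dominant trait locus
#'   (scaffold index and bp).
#' @param parentHeterozygosity probability a site is heterozygous in a parent.
#' @param recombinationRate crossover rate in cM per Mb.
#' @param nOffspring F1 population size phenotyped before pooling.
#' @param nOffspringPerPool integer(2): sizes of the (carrier, non-carrier)
#'   bulks, e.g. `c(28L, 27L)` red/green.
#' @param meanDepth mean sequencing depth per site per pool (Poisson).
#' @param sequencingError per-read probability of reporting the wrong allele.
#' @param referenceMode `"mosaic"` (reference switches between the two
#'   haplotypes of parent A along each scaffold — the pseudoexchange model)
#'   or `"parental"` (reference is parent A's haplotype 1 throughout).
#' @param mosaicSwitchRate expected reference-haplotype switches per Mb.
#' @param penetrance probability the phenotype follows the trait genotype.
#' @param crossType `"RrXrr"` (default: only parent A carries the dominant
#'   allele, heterozygously) or `"RrXRr"` (both parents heterozygous).
#' @param seed integer seed; `NA` lets [simulateCross()] draw one.
#'
#' @return A `CrossSimConfig` object.
#' @examples
#' CrossSimConfig(nScaffolds = 1L, scaffoldLength = 1e5, qtlPosition = 5e4,
#'                seed = 7L)
#' @seealso [simulateCross()], [powerExperiment()]
#' @aliases CrossSimConfig-class
#' @export
CrossSimConfig <- function(nScaffolds = 5L, scaffoldLength = 2e6,
                           snpDensity = 0.002, qtlScaffold = 1L,
                           qtlPosition = 1e6, parentHeterozygosity = 0.4,
                           recombinationRate = 50, nOffspring = 100L,
                           nOffspringPerPool = c(28L, 27L), meanDepth = 20,
                           sequencingError = 0.005,
                           referenceMode = c("mosaic", "parental"),
                           mosaicSwitchRate = 5, penetrance = 1,
                           crossType = c("RrXrr", "RrXRr"),
                           seed = NA_integer_) {
    .CrossSimConfig(nScaffolds = as.integer(nScaffolds),
                    scaffoldLength = as.numeric(scaffoldLength),
                    snpDensity = as.numeric(snpDensity),
                    qtlScaffold = as.integer(qtlScaffold),
                    qtlPosition = as.numeric(qtlPosition),
                    parentHeterozygosity = as.numeric(parentHeterozygosity),
                    recombinationRate = as.numeric(recombinationRate),
                    nOffspring = as.integer(nOffspring),
                    nOffspringPerPool = as.integer(nOffspringPerPool),
                    meanDepth = as.numeric(meanDepth),
                    sequencingError = as.numeric(sequencingError),
                    referenceMode = match.arg(referenceMode),
                    mosaicSwitchRate = as.numeric(mosaicSwitchRate),
                    penetrance = as.numeric(penetrance),
                    crossType = match.arg(crossType),
                    seed = as.integer(seed))
}

.CrossSim <- setClass("CrossSim",
    representation(variants = "PooledVariants", truth = "list",
                   config = "CrossSimConfig", seqlengths = "integer"))

#' @name CrossSim-class
#' @title Result bundle of a simulated cross
#'
#' @description Holds the simulated [PooledVariants] together with the ground
#' truth needed for parameter-recovery and power experiments: the trait-locus
#' location, per-offspring phenotypes, the pooled offspring indices, the
#' mosaic-reference breakpoints per scaffold, and the seed actually used.
#' Produced by [simulateCross()].
#'
#' @aliases CrossSim
#' @exportClass CrossSim
NULL
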