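.scafNames <- function(config)
    sprintf("scaffold_%d", seq_len(config@nScaffolds))

#' Simulate two phased heterozygous parental genomes
#'
#' Draws a shared SNP map (site count Poisson in the scaffold length times
#' `snpDensity`, positions uniform without replacement) and, independently
#' per parent and site, a phased genotype: heterozygous with probability
#' `parentHeterozygosity` (alleles 0/1 in random phase), otherwise
#' homozygous for a random allele. The dominant trait allele (coded 1) is
#' placed at `qtlPosition` on `qtlScaffold`: heterozygous in parent A and,
#' under `"RrXRr"`, in parent B too; under `"RrXrr"` parent B is homozygous
#' 0/0 there.
#'
#' Uses the current RNG state; callers wanting reproducibility seed first
#' (as [simulateCross()] does from `config@seed`).
#'
#' @param config a [CrossSimConfig].
#' @return a list with `positions` (per-scaffold integer vectors), `parentA`
#'   and `parentB` (per-scaffold site x 2 haplotype matrices of 0/1),
#'   `qtlScaffold`, `qtlSite` (row index of the trait locus).
#' @seealso [simulateOffspring()], [simulateCross()]
#' @export
simulateParents <- function(config) {
    stopifnot(is(config, "CrossSimConfig"))
    L <- config@scaffoldLength
    positions <- vector("list", config@nScaffolds)
    parentA <- vector("list", config@nScaffolds)
    parentB <- vector("list", config@nScaffolds)
    for (i in seq_len(config@nScaffolds)) {
        nSites <- rpois(1L, config@snpDensity * L)
        pos <- sort(sample.int(as.integer(L), min(nSites, L)))
        if (i == config@qtlScaffold)
            pos <- sort(unique(c(pos, as.integer(config@qtlPosition))))
        if (length(pos) == 0L)
            stop("zero segregating sites simulated; increase 'snpDensity'")
        positions[[i]] <- pos
        drawParent <- function(n) {
            het <- runif(n) < config@parentHeterozygosity
            homAllele <- rbinom(n, 1L, 0.5)
            phase <- rbinom(n, 1L, 0.5)          # which hap gets allele 1
            h1 <- ifelse(het, phase, homAllele)
            h2 <- ifelse(het, 1L - phase, homAllele)
            cbind(h1, h2, deparse.level = 0L)
        }
        parentA[[i]] <- drawParent(length(pos))
        parentB[[i]] <- drawParent(length(pos))
    }
    qs <- config@qtlScaffold
    qi <- match(as.integer(config@qtlPosition), positions[[qs]])
    # trait locus genotypes: allele 1 = dominant carrier allele
    parentA[[qs]][qi, ] <- sample(c(1L, 0L))
    parentB[[qs]][qi, ] <- if (config@crossType == "RrXRr")
        sample(c(1L, 0L)) else c(0L, 0L)
    list(positions = positions, parentA = parentA, parentB = parentB,
         qtlScaffold = qs, qtlSite = qi)
}

# one recombinant gamete: vector of alleles along one scaffold
.gamete <- function(hap, pos, L, morgans) {
    k <- rpois(1L, morgans)
    h <- sample.int(2L, 1L)
    if (k == 0L) return(hap[, h])
    xo <- sort(runif(k, 0, L))
    seg <- findInterval(pos, xo)          # 0..k crossovers before each site
    idx <- 1L + (h - 1L + seg) %% 2L
    hap[cbind(seq_along(pos), idx)]
}

#' Simulate F1 offspring from two parental genomes
#'
#' Each offspring receives one recombinant gamete per parent per scaffold;
#' crossovers follow a Poisson process with mean equal to the scaffold's
#' genetic length in Morgans (`recombinationRate` cM/Mb). The phenotype is
#' "carrier" (red) iff the offspring has at least one copy of the dominant
#' trait allele, flipped with probability `1 − penetrance`.
#'
#' @param parents output of [simulateParents()].
#' @param config the same [CrossSimConfig].
#' @return a list with `gameteA`/`gameteB` (per-scaffold site x offspring
#'   0/1 matrices) and `phenotype` (logical, TRUE = carrier).
#' @export
simulateOffspring <- function(parents, config) {
    stopifnot(is(config, "CrossSimConfig"))
    L <- config@scaffoldLength
    morgans <- config@recombinationRate * (L / 1e6) / 100
    nOff <- config@nOffspring
    gameteA <- vector("list", config@nScaffolds)
    gameteB <- vector("list", config@nScaffolds)
    for (i in seq_len(config@nScaffolds)) {
        pos <- parents$positions[[i]]
        gameteA[[i]] <- matrix(vapply(seq_len(nOff), function(j)
            .gamete(parents$parentA[[i]], pos, L, morgans),
            integer(length(pos))), nrow = length(pos))
        gameteB[[i]] <- matrix(vapply(seq_len(nOff), function(j)
            .gamete(parents$parentB[[i]], pos, L, morgans),
            integer(length(pos))), nrow = length(pos))
    }
    qs <- parents$qtlScaffold; qi <- parents$qtlSite
    dosage <- gameteA[[qs]][qi, ] + gameteB[[qs]][qi, ]
    carrier <- dosage >= 1L
    flip <- runif(nOff) > config@penetrance
    list(gameteA = gameteA, gameteB = gameteB,
         phenotype = xor(carrier, flip))
}

#' Pool offspring by phenotype and simulate pooled sequencing
#'
#' Forms the carrier bulk (pool A, `nOffspringPerPool[1]` offspring) and the
#' non-carrier bulk (pool B, `nOffspringPerPool[2]`), then sequences each
#' site: the pool's true non-reference allele frequency is the mean allele
#' dosage over pooled offspring measured against the reference sequence.
#' In `"parental"` mode the reference is parent A's haplotype 1 everywhere.
#' In `"mosaic"` mode the reference switches between parent A's two
#' haplotypes at breakpoints drawn as a Poisson process with
#' `mosaicSwitchRate` switches per Mb, flipping which allele is "alt"
#' segment by segment — the pseudoexchange effect, which randomly flips the
#' sign of per-site Delta(SNP-index) without changing its magnitude.
#' Read depth per site and pool is Poisson(`meanDepth`); alt read counts are
#' Binomial(depth, freq) with the frequency moved toward 0.5 by
#' `sequencingError`.
#'
#' @param offspring output of [simulateOffspring()].
#' @param parents output of [simulateParents()].
#' @param config the same [CrossSimConfig].
#' @return a list with `variants` (a [PooledVariants]; pool A = carrier
#'   bulk, named `pool_red`/`pool_green`), `poolA`/`poolB` (offspring
#'   indices), and `breakpoints` (per-scaffold reference switch positions).
#' @export
buildPoolsAndSequence <- function(offspring, parents, config) {
    stopifnot(is(config, "CrossSimConfig"))
    nRed <- config@nOffspringPerPool[1L]
    nGreen <- config@nOffspringPerPool[2L]
    redIdx <- which(offspring$phenotype)
    greenIdx <- which(!offspring$phenotype)
    if (length(redIdx) < nRed || length(greenIdx) < nGreen)
        stop("not enough offspring of each phenotype to fill the pools (",
             length(redIdx), " carriers, ", length(greenIdx),
             " non-carriers)")
    redIdx <- redIdx[seq_len(nRed)]
    greenIdx <- greenIdx[seq_len(nGreen)]

    L <- config@scaffoldLength
    scafs <- .scafNames(config)
    breakpoints <- vector("list", config@nScaffolds)
    names(breakpoints) <- scafs
    allScaf <- allPos <- allRef <- allAlt <- list()
    allAdA <- allAdB <- list()
    bases <- c("A", "C", "G", "T")

    for (i in seq_len(config@nScaffolds)) {
        pos <- parents$positions[[i]]
        n <- length(pos)
        # reference allele per site, from parent A's haplotypes
        if (config@referenceMode == "parental") {
            refAllele <- parents$parentA[[i]][, 1L]
            breakpoints[[i]] <- numeric(0L)
        } else {
            k <- rpois(1L, config@mosaicSwitchRate * L / 1e6)
            bp <- sort(runif(k, 0, L))
            startHap <- sample.int(2L, 1L)
            hapIdx <- 1L + (startHap - 1L + findInterval(pos, bp)) %% 2L
            refAllele <- parents$parentA[[i]][cbind(seq_len(n), hapIdx)]
            breakpoints[[i]] <- bp
        }
        poolFreq <- function(idx) {
            D <- offspring$gameteA[[i]][, idx, drop = FALSE] +
                offspring$gameteB[[i]][, idx, drop = FALSE]
            p1 <- rowSums(D) / (2 * length(idx))   # freq of allele 1
            ifelse(refAllele == 1L, 1 - p1, p1)
        }
        seqPool <- function(freq) {
            depth <- rpois(n, config@meanDepth)
            e <- config@sequencingError
            altReads <- rbinom(n, depth, freq * (1 - e) + (1 - freq) * e)
            cbind(ref = depth - altReads, alt = altReads)
        }
        adA <- seqPool(poolFreq(redIdx))
        adB <- seqPool(poolFreq(greenIdx))
        refBase <- sample(bases, n, replace = TRUE)
        altBase <- vapply(refBase, function(b)
            sample(setdiff(bases, b), 1L), character(1L), USE.NAMES = FALSE)
        allScaf[[i]] <- rep(scafs[i], n); allPos[[i]] <- pos
        allRef[[i]] <- refBase; allAlt[[i]] <- altBase
        allAdA[[i]] <- adA; allAdB[[i]] <- adB
    }
    adA <- do.call(rbind, allAdA); adB <- do.call(rbind, allAdB)
    sl <- setNames(rep(as.integer(L), config@nScaffolds), scafs)
    variants <- PooledVariants(
        scaffold = unlist(allScaf), position = unlist(allPos),
        ref = unlist(allRef), alt = unlist(allAlt),
        adRefA = adA[, "ref"], adAltA = adA[, "alt"],
        adRefB = adB[, "ref"], adAltB = adB[, "alt"],
        poolNames = c("pool_red", "pool_green"), seqlengths = sl)
    list(variants = variants, poolA = redIdx, poolB = greenIdx,
         breakpoints = breakpoints)
}

#' Simulate a full pooled-sequencing experiment from an F1 cross
#'
#' Runs [simulateParents()], [simulateOffspring()] and
#' [buildPoolsAndSequence()] under one seed and bundles the result with its
#' ground truth. The same seed reproduces the identical dataset bit for bit;
#' when `config@seed` is `NA` a seed is drawn and recorded in the truth.
#'
#' @param config a [CrossSimConfig].
#' @return a [CrossSim-class] object.
#' @examples
#' sim <- simulateCross(CrossSimConfig(nScaffolds = 1L, scaffoldLength = 2e5,
#'                                     qtlPosition = 1e5, nOffspring = 60L,
#'                                     nOffspringPerPool = c(12L, 12L),
#'                                     seed = 42L))
#' sim
#' @seealso [writeSimBundle()], [powerExperiment()]
#' @export
simulateCross <- function(config) {
    stopifnot(is(config, "CrossSimConfig"))
    seed <- config@seed
    if (is.na(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    set.seed(seed)
    parents <- simulateParents(config)
    offspring <- simulateOffspring(parents, config)
    pools <- buildPoolsAndSequence(offspring, parents, config)
    truth <- list(qtlScaffold = .scafNames(config)[config@qtlScaffold],
                  qtlPosition = as.integer(config@qtlPosition),
                  phenotype = offspring$phenotype,
                  poolA = pools$poolA, poolB = pools$poolB,
                  breakpoints = pools$breakpoints,
                  seed = seed)
    .CrossSim(variants = pools$variants, truth = truth, config = config,
              seqlengths = setNames(rep(as.integer(config@scaffoldLength),
                                        config@nScaffolds),
                                    .scafNames(config)))
}

#' Write a simulated dataset bundle to disk
#'
#' Emits a VCF with the two pool samples carrying AD fields, a scaffold
#' length table (`.fai`-style) and a ground-truth TSV (trait locus, pool
#' sizes, seed, reference breakpoints) — everything [readVariants()] and
#' [runQtlseq()] need, with nothing external.
#'
#' @param sim a [CrossSim-class] from [simulateCross()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default `"sim"`).
#' @return named character vector of the files written, invisibly.
#' @export
writeSimBundle <- function(sim, dir, prefix = "sim") {
    stopifnot(is(sim, "CrossSim"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    vcf <- file.path(dir, paste0(prefix, ".vcf"))
    fai <- file.path(dir, paste0(prefix, ".scaffolds.tsv"))
    truth <- file.path(dir, paste0(prefix, ".truth.tsv"))
    writeVariants(sim@variants, vcf, "vcf")
    writeScaffoldLengths(sim@seqlengths, fai)
    tt <- sim@truth
    bp <- vapply(tt$breakpoints, function(b)
        paste(round(b), collapse = ","), character(1L))
    tab <- data.frame(
        key = c("qtl_scaffold", "qtl_position", "seed",
                "n_pool_red", "n_pool_green",
                paste0("breakpoints_", names(tt$breakpoints))),
        value = c(tt$qtlScaffold, tt$qtlPosition, tt$seed,
                  length(tt$poolA), length(tt$poolB), bp))
    write.table(tab, truth, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(vcf = vcf, scaffolds = fai, truth = truth))
}
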