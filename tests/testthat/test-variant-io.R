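test_that("SNP-index hits its definitional extremes and ratios", {
    expect_identical(computeSnpIndex(20, 0), 1)
    expect_identical(computeSnpIndex(0, 20), 0)
    expect_equal(computeSnpIndex(3, 7), 0.3)
    expect_true(is.na(computeSnpIndex(0, 0)))
    expect_error(computeSnpIndex(-1, 5), "non-negative")
    # vectorized, always in [0,1] or missing
    a <- sample(0:50, 200, replace = TRUE)
    r <- sample(0:50, 200, replace = TRUE)
    idx <- computeSnpIndex(a, r)
    ok <- !is.na(idx)
    expect_true(all(idx[ok] >= 0 & idx[ok] <= 1))
    expect_true(all(idx[a > 0 & r == 0] == 1))
    expect_true(all(idx[a == 0 & r > 0] == 0))
    expect_identical(is.na(idx), a + r == 0)
})

test_that("VCF with AD fields is parsed into per-pool indices", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=s1,length=300000>",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "red", "green", sep = "\t"),
        "s1\t100\t.\tA\tG\t.\tPASS\t.\tAD\t0,20\t10,10",
        "s1\t300\t.\tG\tA\t.\tPASS\t.\tAD\t0,0\t3,9"), vcf)
    pv <- readVariants(vcf, "red", "green")
    expect_s4_class(pv, "PooledVariants")
    expect_length(pv, 2L)
    expect_identical(poolNames(pv), c("red", "green"))
    expect_equal(snpIndex(pv, "A"), c(1, NA))
    expect_equal(snpIndex(pv, "B"), c(0.5, 0.75))
    expect_error(readVariants(vcf, "red", "blue"), "not in VCF")
})

test_that("multi-allelic sites collapse to the best-supported alt allele", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=s1,length=300000>",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "a", "b", sep = "\t"),
        "s1\t200\t.\tC\tT,G\t.\tPASS\t.\tAD\t5,10,2\t4,8,1"), vcf)
    expect_message(pv <- readVariants(vcf, "a", "b"), "multi-allelic")
    gr <- variantRanges(pv)
    expect_identical(gr$alt, "T")           # summed support 18 vs 3
    expect_identical(gr$adAltA, 10L)
    expect_identical(gr$adRefB, 4L)
})

test_that("an empty or malformed input fails loudly", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "a", "b", sep = "\t")), vcf)
    expect_error(readVariants(vcf, "a", "b"), "no parsable")
    tab <- tempfile(fileext = ".tsv")
    writeLines(c("scaffold\tpos\tref\talt\ta_ref\ta_alt\tb_ref\tb_alt",
                 "s1\t10\tA\tG\t5\tfive\t5\t5"), tab)
    expect_error(readVariants(tab), "line 2")
    expect_error(readVariants(tempfile()), "not found")
})

test_that("simulator VCF and table outputs round-trip exactly", {
    sim <- simulateCross(CrossSimConfig(nScaffolds = 2L, scaffoldLength = 3e4,
                                        snpDensity = 1e-3, qtlPosition = 1.5e4,
                                        nOffspring = 30L,
                                        nOffspringPerPool = c(6L, 6L),
                                        seed = 99L))
    pv <- simVariants(sim)
    expect_gte(length(pv), 30L)
    for (fmt in c("vcf", "table")) {
        f <- tempfile(fileext = if (fmt == "vcf") ".vcf" else ".tsv")
        writeVariants(pv, f, fmt)
        back <- readVariants(f, poolNames(pv)[1L], poolNames(pv)[2L],
                             format = fmt)
        expect_identical(poolNames(back), poolNames(pv))
        expect_equal(as.data.frame(back), as.data.frame(pv))
    }
})

test_that("scaffold-length tables round-trip in .fai style", {
    sl <- c(s1 = 300000L, s2 = 150000L)
    f <- tempfile()
    writeScaffoldLengths(sl, f)
    expect_identical(readScaffoldLengths(f), sl)
})

test_that("quality filters drop by index, depth and missingness rules", {
    mk <- function(aR, aA, bR, bA)
        PooledVariants("s1", seq_along(aR), "A", "G", aR, aA, bR, bA)
    pol <- FilterPolicy()   # minIndex 0.3, minDepth 7, both_pools_below

    # low index in both pools -> dropped; informative in one pool -> kept
    pv <- mk(c(18L, 2L), c(2L, 18L), c(16L, 16L), c(4L, 4L))
    res <- applyFilters(pv, pol)       # indexA 0.1/0.9, indexB 0.2/0.2
    expect_length(res$kept, 1L)
    expect_identical(as.character(res$reasons), "low_index")
    expect_equal(snpIndex(res$kept, "A"), 0.9)

    # either_pool_below drops the informative-in-one-pool record too
    res2 <- applyFilters(pv, FilterPolicy(indexRule = "either_pool_below"))
    expect_length(res2$kept, 0L)

    # total depth below 7 in one pool -> low_depth
    pv3 <- mk(5L, 15L, 2L, 3L)
    res3 <- applyFilters(pv3, pol)
    expect_identical(as.character(res3$reasons), "low_depth")

    # zero-depth pool -> missing_index wins over other reasons
    pv4 <- mk(0L, 0L, 10L, 10L)
    res4 <- applyFilters(pv4, pol)
    expect_identical(as.character(res4$reasons), "missing_index")

    # partition: kept + dropped == input, order preserved
    pv5 <- randomVariants(300L, c(s1 = 1e5), seed = 7L, depth = 9L)
    res5 <- applyFilters(pv5, pol)
    expect_identical(length(res5$kept) + length(res5$dropped), length(pv5))
    expect_identical(length(res5$dropped), length(res5$reasons))
    merged <- sort(c(variantRanges(res5$kept), variantRanges(res5$dropped)))
    expect_equal(as.data.frame(merged), as.data.frame(variantRanges(pv5)))
})

test_that("filtering is idempotent", {
    pv <- randomVariants(500L, c(s1 = 1e5, s2 = 5e4), seed = 3L, depth = 10L)
    for (rule in c("both_pools_below", "either_pool_below")) {
        pol <- FilterPolicy(indexRule = rule)
        once <- applyFilters(pv, pol)$kept
        twice <- applyFilters(once, pol)
        expect_length(twice$dropped, 0L)
        expect_identical(length(twice$kept), length(once))
    }
})
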