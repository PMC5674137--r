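#' SNP-index from allele depths
#'
#' The SNP-index is the ratio between the number of reads carrying the
#' non-reference (alternate) allele and the total number of reads covering
#' the site: `alt/(alt+ref)`. It equals 1 when all short reads differ from
#' the reference and 0 when all short reads match the reference; it is `NA`
#' (missing) when the site has no coverage.
#'
#' @param altDepth,refDepth non-negative read counts (vectorized; `NA`
#'   counts give a missing index).
#' @return numeric vector in \[0,1\], `NA` where total depth is zero.
#' @examples
#' computeSnpIndex(20, 0)  # 1
#' computeSnpIndex(0, 20)  # 0
#' computeSnpIndex(3, 7)   # 0.3
#' computeSnpIndex(0, 0)   # NA
#' @export
computeSnpIndex <- function(altDepth, refDepth) {
    if (any(altDepth < 0, na.rm = TRUE) || any(refDepth < 0, na.rm = TRUE))
        stop("read depths must be non-negative")
    tot <- altDepth + refDepth
    out <- altDepth / tot
    out[!is.na(tot) & tot == 0] <- NA_real_
    out
}

#' Read pooled variant calls from VCF or a tab-separated table
#'
#' Builds a [PooledVariants] object from a multi-sample VCF with per-sample
#' allele depths (`AD`) or from a plain tab-separated table with columns
#' `scaffold, pos, ref, alt, a_ref, a_alt, b_ref, b_alt`. Records are sorted
#' by (scaffold, position). Multi-allelic VCF sites are reduced to the
#' alternate allele with the largest summed depth across both pools (with a
#' message); sites with zero depth in a pool carry a missing SNP-index for
#' that pool.
#'
#' @param path input file; `.vcf`/`.vcf.gz`/`.vcf.bgz` are treated as VCF,
#'   anything else as a table unless `format` says otherwise.
#' @param poolA,poolB sample names of the two bulks. For a VCF with exactly
#'   two samples they default to the first and second sample.
#' @param format `"auto"`, `"vcf"` or `"table"`.
#' @return a [PooledVariants] object (pool A first; sign of Delta follows).
#' @examples
#' tab <- data.frame(scaffold = "s1", pos = 100L, ref = "A", alt = "G",
#'                   a_ref = 0L, a_alt = 20L, b_ref = 10L, b_alt = 10L)
#' tf <- tempfile(fileext = ".tsv")
#' write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' pv <- readVariants(tf)
#' snpIndex(pv, "A")
#' @seealso [writeVariants()], [applyFilters()]
#' @export
readVariants <- function(path, poolA = NULL, poolB = NULL,
                         format = c("auto", "vcf", "table")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.b?gz)?$", path)) "vcf" else "table"
    if (format == "vcf") .readVariantsVcf(path, poolA, poolB)
    else .readVariantsTable(path, poolA, poolB)
}

.readVariantsVcf <- function(path, poolA, poolB) {
    vcf <- VariantAnnotation::readVcf(path)
    samp <- colnames(vcf)
    if (is.null(poolA) && is.null(poolB)) {
        if (length(samp) != 2L)
            stop("VCF has ", length(samp),
                 " samples; name 'poolA' and 'poolB' explicitly")
        poolA <- samp[1L]; poolB <- samp[2L]
    }
    miss <- setdiff(c(poolA, poolB), samp)
    if (length(miss))
        stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
        stop("VCF lacks the per-sample AD (allele depth) FORMAT field")
    if (nrow(vcf) == 0L) stop("no parsable variant records in ", path)

    ad <- VariantAnnotation::geno(vcf)$AD
    rr <- SummarizedExperiment::rowRanges(vcf)
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altList)

    getAD <- function(sample, k) {
        # k = allele slot: 1 ref, 1+j for alt j; missing/short AD -> 0 depth
        vapply(seq_len(nrow(vcf)), function(i) {
            v <- ad[i, sample][[1L]]
            if (is.null(v) || length(v) < k[i] || is.na(v[k[i]])) 0L
            else as.integer(v[k[i]])
        }, integer(1L))
    }
    one <- rep(1L, nrow(vcf))
    # choose, per site, the alt allele best supported across both pools
    altPick <- rep(1L, nrow(vcf))
    multi <- which(nAlt > 1L)
    if (length(multi)) {
        for (i in multi) {
            support <- vapply(seq_len(nAlt[i]), function(j) {
                s <- 0L
                for (sm in c(poolA, poolB)) {
                    v <- ad[i, sm][[1L]]
                    if (!is.null(v) && length(v) >= j + 1L && !is.na(v[j + 1L]))
                        s <- s + as.integer(v[j + 1L])
                }
                s
            }, integer(1L))
            altPick[i] <- which.max(support)
        }
        message(length(multi), " multi-allelic site(s): keeping the ",
                "most-supported alternate allele at each")
    }
    altChar <- vapply(seq_len(nrow(vcf)), function(i)
        as.character(altList[[i]][altPick[i]]), character(1L))

    sl <- seqlengths(vcf)
    if (all(is.na(sl))) sl <- NULL
    PooledVariants(scaffold = as.character(seqnames(rr)),
                   position = start(rr),
                   ref = as.character(VariantAnnotation::ref(vcf)),
                   alt = altChar,
                   adRefA = getAD(poolA, one),
                   adAltA = getAD(poolA, altPick + 1L),
                   adRefB = getAD(poolB, one),
                   adAltB = getAD(poolB, altPick + 1L),
                   poolNames = c(poolA, poolB),
                   seqlengths = sl)
}

.tableCols <- c("scaffold", "pos", "ref", "alt",
                "a_ref", "a_alt", "b_ref", "b_alt")

.readVariantsTable <- function(path, poolA, poolB) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(.tableCols, colnames(tab))
    if (length(miss))
        stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(tab) == 0L) stop("no parsable variant records in ", path)
    for (cc in c("pos", "a_ref", "a_alt", "b_ref", "b_alt")) {
        v <- suppressWarnings(as.numeric(tab[[cc]]))
        bad <- which(is.na(v) & !is.na(tab[[cc]]) & tab[[cc]] != "NA")
        if (length(bad))
            stop("malformed '", cc, "' at line ", bad[1L] + 1L, " of ", path)
        tab[[cc]] <- as.integer(v)
    }
    PooledVariants(scaffold = tab$scaffold, position = tab$pos,
                   ref = tab$ref, alt = tab$alt,
                   adRefA = tab$a_ref, adAltA = tab$a_alt,
                   adRefB = tab$b_ref, adAltB = tab$b_alt,
                   poolNames = c(poolA %||% "poolA", poolB %||% "poolB"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pooled variants to VCF or a tab-separated table
#'
#' The VCF writer emits a minimal VCF 4.2 with one `AD` FORMAT field per
#' pool sample and `contig` header lines when scaffold lengths are known;
#' [readVariants()] reads it back unchanged. The table format is the
#' eight-column layout documented in [readVariants()].
#'
#' @param x a [PooledVariants] object.
#' @param path output file.
#' @param format `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @seealso [readVariants()]
#' @export
writeVariants <- function(x, path, format = c("vcf", "table")) {
    format <- match.arg(format)
    gr <- variantRanges(x)
    if (format == "table") {
        tab <- data.frame(scaffold = as.character(seqnames(gr)),
                          pos = start(gr), ref = gr$ref, alt = gr$alt,
                          a_ref = gr$adRefA, a_alt = gr$adAltA,
                          b_ref = gr$adRefB, b_alt = gr$adAltB)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(path))
    }
    sl <- seqlengths(gr)
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##source=absQTLseq-", packageVersion("absQTLseq")))
    if (length(sl) && !all(is.na(sl)))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                              names(sl)[!is.na(sl)], sl[!is.na(sl)]))
    hdr <- c(hdr,
             paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                    "Description=\"Allelic depths for the ref and alt alleles\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", poolNames(x)), collapse = "\t"))
    adStr <- function(r, a) ifelse(is.na(r) | is.na(a), ".",
                                   paste(r, a, sep = ","))
    body <- paste(as.character(seqnames(gr)), start(gr), ".", gr$ref, gr$alt,
                  ".", "PASS", ".", "AD",
                  adStr(gr$adRefA, gr$adAltA), adStr(gr$adRefB, gr$adAltB),
                  sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read and write scaffold lengths
#'
#' `readScaffoldLengths` accepts a FASTA `.fai` index or any whitespace- or
#' tab-separated file whose first two columns are scaffold name and length.
#'
#' @param path two-or-more-column text file (`.fai` compatible).
#' @return named integer vector of scaffold lengths.
#' @examples
#' tf <- tempfile()
#' writeLines(c("s1\t300000", "s2\t150000"), tf)
#' readScaffoldLengths(tf)
#' @export
readScaffoldLengths <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expected at least two columns (name, length)")
    len <- suppressWarnings(as.integer(tab[[2L]]))
    if (anyNA(len)) stop("non-numeric scaffold length in ", path)
    setNames(len, as.character(tab[[1L]]))
}

#' @rdname readScaffoldLengths
#' @param lengths named integer vector.
#' @export
writeScaffoldLengths <- function(lengths, path) {
    write.table(data.frame(names(lengths), as.integer(lengths)), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Apply low-quality SNP filters to pooled variants
#'
#' Partitions the input into kept and dropped records under a
#' [FilterPolicy]: sites whose SNP-index is missing in one of the pools,
#' sites with total read depth below `minDepth` in either pool, and sites
#' whose SNP-index falls below `minIndex` under the policy's index rule are
#' excluded. Each dropped record carries exactly one reason tag
#' (`missing_index`, `low_depth` or `low_index`, in that precedence);
#' record order is preserved and filtering the kept set again drops nothing.
#'
#' @param x a [PooledVariants] object.
#' @param policy a [FilterPolicy].
#' @param ... unused.
#' @return a list with elements `kept` and `dropped` (both
#'   `PooledVariants`) and `reasons`, a factor parallel to `dropped`.
#' @examples
#' pv <- PooledVariants("s1", c(1L, 2L), "A", "G",
#'                      adRefA = c(18L, 9L), adAltA = c(2L, 1L),
#'                      adRefB = c(2L, 1L),  adAltB = c(18L, 9L))
#' applyFilters(pv)$reasons   # second site: low_depth
#' @rdname applyFilters
#' @export
setMethod("applyFilters", "PooledVariants", function(x, policy = FilterPolicy(), ...) {
    stopifnot(is(policy, "FilterPolicy"))
    gr <- variantRanges(x)
    iA <- gr$indexA; iB <- gr$indexB
    dA <- gr$adRefA + gr$adAltA
    dB <- gr$adRefB + gr$adAltB
    reason <- rep(NA_character_, length(gr))

    belowA <- !is.na(iA) & iA < policy@minIndex
    belowB <- !is.na(iB) & iB < policy@minIndex
    lowIndex <- if (policy@indexRule == "both_pools_below")
        belowA & belowB else belowA | belowB
    reason[lowIndex] <- "low_index"
    lowDepth <- (!is.na(dA) & dA < policy@minDepth) |
        (!is.na(dB) & dB < policy@minDepth)
    reason[lowDepth] <- "low_depth"
    if (policy@dropIfMissingInOnePool)
        reason[is.na(iA) | is.na(iB)] <- "missing_index"

    drop <- !is.na(reason)
    list(kept = x[!drop], dropped = x[drop],
         reasons = factor(reason[drop],
                          levels = c("missing_index", "low_depth", "low_index")))
})
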