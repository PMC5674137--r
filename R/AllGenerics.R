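#' @rdname snpIndex
#' @export
setGeneric("snpIndex", function(x, pool = c("A", "B")) standardGeneric("snpIndex"))

#' @rdname deltaIndex
#' @export
setGeneric("deltaIndex", function(x) standardGeneric("deltaIndex"))

#' @rdname deltaIndex
#' @export
setGeneric("absDeltaIndex", function(x) standardGeneric("absDeltaIndex"))

#' @rdname poolNames
#' @export
setGeneric("poolNames", function(x) standardGeneric("poolNames"))

#' @rdname variantRanges
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname windowRanges
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))

#' @rdname applyFilters
#' @export
setGeneric("applyFilters", function(x, policy = FilterPolicy(), ...)
    standardGeneric("applyFilters"))
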