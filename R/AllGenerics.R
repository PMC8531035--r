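## Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param x a pipeline object
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))
#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("pairs", function(x) standardGeneric("pairs"))
#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname accessors
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Accessors for pipeline objects
#'
#' \code{records} returns the per-variant table of a \linkS4class{SumStats};
#' \code{trait} its label. \code{ldMatrix} returns the signed correlation
#' matrix; \code{variantIds} the ordered variant ids. \code{pairs} returns the
#' harmonized effect table of an \linkS4class{InstrumentSet}. \code{estimate}
#' returns a one-row (or per-exposure) data.frame summary of an
#' \linkS4class{MREstimate} / \linkS4class{MVMREstimate}. \code{posterior}
#' returns the PP0..PP4 vector of a \linkS4class{ColocResult}.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("records", "SumStats", function(x) x@records)
#' @rdname accessors
setMethod("trait", "SumStats", function(x) x@trait)
#' @rdname accessors
setMethod("ldMatrix", "LDMatrix", function(x) x@r)
#' @rdname accessors
setMethod("ldMatrix", "InstrumentSet", function(x) x@ld@r)
#' @rdname accessors
setMethod("variantIds", "LDMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("variantIds", "InstrumentSet", function(x) x@ld@variants)
#' @rdname accessors
setMethod("variantIds", "SumStats", function(x) {
  r <- x@records
  variantId(r$chrom, r$pos, r$effect_allele, r$other_allele)
})
#' @rdname accessors
setMethod("pairs", "InstrumentSet", function(x) x@pairs)
#' @rdname accessors
setMethod("estimate", "MREstimate", function(x) {
  data.frame(unit = x@unit, family = x@family, effects = x@effects,
             n_snps = as.integer(x@nSnps), beta = x@beta, se = x@se,
             or = x@or, ci_low = exp(x@ciLow), ci_high = exp(x@ciHigh),
             pvalue = x@pvalue, intercept = x@intercept,
             intercept_se = x@interceptSE, q = x@q,
             q_df = as.integer(x@qDf), q_pvalue = x@qPvalue,
             stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("estimate", "MVMREstimate", function(x) {
  cbind(unit = x@unit, x@estimates, n_snps = as.integer(x@nSnps),
        q = x@q, q_df = as.integer(x@qDf), q_pvalue = x@qPvalue)
})
#' @rdname accessors
setMethod("posterior", "ColocResult", function(x) x@pp)
#' @rdname accessors
setMethod("nVariants", "ColocResult", function(x) x@nVariants)
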