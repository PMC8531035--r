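## Central S4 containers for the drug-target MR pipeline.
##
## Conventions: GRCh37 coordinates, 1-based inclusive; quantitative trait
## effects are per SD of the phenotype per effect allele; binary outcomes on
## the log-odds scale.

REQUIRED_RECORD_COLS <- c("chrom", "pos", "effect_allele", "other_allele",
                          "beta", "se", "pvalue", "eaf", "n")

#' SumStats: per-variant GWAS summary statistics for one trait
#'
#' Holds one trait's association records together with scale metadata.
#' Records are a data.frame with columns \code{chrom}, \code{pos},
#' \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#' \code{pvalue}, \code{eaf}, \code{n} and optionally \code{rsid}.
#' Coordinates are 1-based inclusive on GRCh37.
#'
#' @slot trait trait label, e.g. "LDL-C"
#' @slot traitType "quantitative" or "binary"
#' @slot scale "per-SD" (quantitative) or "log-odds" (binary)
#' @slot records data.frame of association records (one row per variant)
#' @exportClass SumStats
setClass("SumStats",
  representation(trait = "character", traitType = "character",
                 scale = "character", records = "data.frame"))

setValidity("SumStats", function(object) {
  msg <- character(0)
  rec <- object@records
  missing_cols <- setdiff(REQUIRED_RECORD_COLS, names(rec))
  if (length(missing_cols))
    msg <- c(msg, paste("records missing columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (!object@scale %in% c("per-SD", "log-odds"))
    msg <- c(msg, "scale must be 'per-SD' or 'log-odds'")
  if (object@traitType == "quantitative" && object@scale != "per-SD")
    msg <- c(msg, "quantitative traits must be on the per-SD scale")
  if (object@traitType == "binary" && object@scale != "log-odds")
    msg <- c(msg, "binary traits must be on the log-odds scale")
  if (nrow(rec) > 0 && length(msg) == 0) {
    if (any(rec$se <= 0)) msg <- c(msg, "all se must be > 0")
    if (any(rec$eaf <= 0 | rec$eaf >= 1)) msg <- c(msg, "eaf must be in (0,1)")
    if (any(rec$pvalue <= 0 | rec$pvalue > 1))
      msg <- c(msg, "pvalue must be in (0,1]")
    if (any(rec$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(toupper(rec$effect_allele) == toupper(rec$other_allele)))
      msg <- c(msg, "effect_allele must differ from other_allele")
    ids <- variantId(rec$chrom, rec$pos, rec$effect_allele, rec$other_allele)
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate variants in records")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SumStats object
#'
#' @param records data.frame of association records (see \linkS4class{SumStats})
#' @param trait trait label
#' @param traitType "quantitative" or "binary"
#' @return a validated \linkS4class{SumStats}
#' @export
SumStats <- function(records, trait, traitType = c("quantitative", "binary")) {
  traitType <- match.arg(traitType)
  scale <- if (traitType == "quantitative") "per-SD" else "log-odds"
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  rownames(records) <- NULL
  new("SumStats", trait = trait, traitType = traitType, scale = scale,
      records = records)
}

#' LDMatrix: signed pairwise correlation over an ordered variant list
#'
#' @slot variants canonical variant ids (chrom:pos:alleleMin:alleleMax)
#' @slot r signed correlation matrix aligned to the effect alleles of variants
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(variants = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  msg <- character(0)
  r <- object@r
  p <- length(object@variants)
  if (!all(dim(r) == c(p, p))) msg <- c(msg, "r must be p x p over variants")
  else if (p > 0) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "r must have unit diagonal")
    if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) msg <- c(msg, "entries must be in [-1,1]")
    ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6) msg <- c(msg, sprintf("smallest eigenvalue %.3g < 0", ev))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LDMatrix
#' @param r square signed correlation matrix
#' @param variants canonical variant ids for the rows/columns of r
#' @return an \linkS4class{LDMatrix}
#' @export
LDMatrix <- function(r, variants = colnames(r)) {
  if (is.null(variants)) pkgError("format_error", "LD matrix needs variant ids")
  r <- as.matrix(r)
  r <- (r + t(r)) / 2       # symmetrize away round-off
  diag(r) <- 1
  dimnames(r) <- list(variants, variants)
  new("LDMatrix", variants = as.character(variants), r = r)
}

#' ReferencePanel: individual-level dosages used to estimate LD
#'
#' @slot dosages individuals x variants matrix of effect-allele dosages in [0,2]
#' @slot variants data.frame of variant keys (chrom, pos, effect_allele,
#'   other_allele)
#' @slot maf per-variant minor-allele frequency in (0, 0.5]
#' @slot info per-variant imputation quality in [0,1]
#' @slot gprob per-variant mean genotype probability in [0,1]
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(dosages = "matrix", variants = "data.frame",
                 maf = "numeric", info = "numeric", gprob = "numeric"))

setValidity("ReferencePanel", function(object) {
  msg <- character(0)
  p <- nrow(object@variants)
  if (ncol(object@dosages) != p) msg <- c(msg, "dosage columns must match variants")
  if (length(object@maf) != p || length(object@info) != p ||
      length(object@gprob) != p)
    msg <- c(msg, "maf/info/gprob must have one entry per variant")
  if (p > 0 && length(msg) == 0) {
    if (any(object@maf <= 0 | object@maf > 0.5))
      msg <- c(msg, "maf must be in (0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#' @param dosages individuals x variants dosage matrix
#' @param variants data.frame with chrom, pos, effect_allele, other_allele
#' @param maf,info,gprob per-variant QC metrics; maf defaults to the empirical
#'   dosage frequency folded to (0, 0.5]
#' @return a \linkS4class{ReferencePanel}
#' @export
ReferencePanel <- function(dosages, variants, maf = NULL,
                           info = rep(1, nrow(variants)),
                           gprob = rep(1, nrow(variants))) {
  dosages <- as.matrix(dosages)
  if (is.null(maf)) {
    eaf <- colMeans(dosages, na.rm = TRUE) / 2
    maf <- pmin(pmax(pmin(eaf, 1 - eaf), 1e-6), 0.5)
  }
  ids <- variantId(variants$chrom, variants$pos,
                   variants$effect_allele, variants$other_allele)
  colnames(dosages) <- ids
  new("ReferencePanel", dosages = dosages, variants = variants,
      maf = as.numeric(maf), info = as.numeric(info),
      gprob = as.numeric(gprob))
}

#' InstrumentSet: harmonized exposure/outcome effects plus their LD submatrix
#'
#' The analysis unit is either genome-wide or a flanked gene region. Pairs and
#' the LD matrix index the same ordered variant list.
#'
#' @slot unit unit label (e.g. "genome-wide" or a gene symbol)
#' @slot exposureTrait,outcomeTrait trait labels
#' @slot pairs data.frame with variant id, bx, sx, by, sy, px, eaf
#' @slot ld \linkS4class{LDMatrix} over the same ordered variants
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(unit = "character", exposureTrait = "character",
                 outcomeTrait = "character", pairs = "data.frame",
                 ld = "LDMatrix"))

setValidity("InstrumentSet", function(object) {
  msg <- character(0)
  need <- c("variant", "bx", "sx", "by", "sy", "px", "eaf")
  missing_cols <- setdiff(need, names(object@pairs))
  if (length(missing_cols))
    msg <- c(msg, paste("pairs missing columns:",
                        paste(missing_cols, collapse = ", ")))
  else if (!identical(as.character(object@pairs$variant), object@ld@variants))
    msg <- c(msg, "pairs and ld must index the same ordered variant list")
  if (length(msg)) msg else TRUE
})

#' Construct an InstrumentSet
#' @param pairs data.frame with columns variant, bx, sx, by, sy, px, eaf
#' @param ld \linkS4class{LDMatrix} over the same ordered variants
#' @param unit analysis-unit label
#' @param exposureTrait,outcomeTrait trait labels
#' @return an \linkS4class{InstrumentSet}
#' @export
InstrumentSet <- function(pairs, ld, unit = "genome-wide",
                          exposureTrait = "exposure",
                          outcomeTrait = "outcome") {
  rownames(pairs) <- NULL
  new("InstrumentSet", unit = unit, exposureTrait = exposureTrait,
      outcomeTrait = outcomeTrait, pairs = pairs, ld = ld)
}

#' MREstimate: a causal effect estimate with model and heterogeneity metadata
#'
#' @slot beta causal slope (log-OR per SD of exposure for a binary outcome)
#' @slot se standard error of beta
#' @slot ciLow,ciHigh 95 percent confidence bounds
#' @slot pvalue two-sided normal p-value
#' @slot or exp(beta)
#' @slot intercept,interceptSE Egger intercept (NA for IVW)
#' @slot q,qDf,qPvalue Cochran's Q heterogeneity statistic
#' @slot nSnps number of instruments
#' @slot family "ivw" or "egger"
#' @slot effects "fixed" or "random"
#' @slot unit analysis-unit label
#' @exportClass MREstimate
setClass("MREstimate",
  representation(beta = "numeric", se = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", pvalue = "numeric", or = "numeric",
                 intercept = "numeric", interceptSE = "numeric",
                 q = "numeric", qDf = "numeric", qPvalue = "numeric",
                 nSnps = "numeric", family = "character",
                 effects = "character", unit = "character"))

setValidity("MREstimate", function(object) {
  msg <- character(0)
  if (!object@family %in% c("ivw", "egger")) msg <- c(msg, "family must be ivw/egger")
  if (!object@effects %in% c("fixed", "random"))
    msg <- c(msg, "effects must be fixed/random")
  if (object@ciLow >= object@ciHigh) msg <- c(msg, "ciLow must be < ciHigh")
  if (object@or <= 0) msg <- c(msg, "or must be positive")
  if (!is.na(object@q) && object@q < -1e-10) msg <- c(msg, "q must be >= 0")
  if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MVMREstimate: multivariable MR joint estimates for several exposures
#'
#' @slot estimates data.frame with exposure, beta, se, ciLow, ciHigh, pvalue, or
#' @slot q,qDf,qPvalue joint heterogeneity (reported as pleiotropy evidence)
#' @slot nSnps number of instruments
#' @slot unit analysis-unit label
#' @exportClass MVMREstimate
setClass("MVMREstimate",
  representation(estimates = "data.frame", q = "numeric", qDf = "numeric",
                 qPvalue = "numeric", nSnps = "numeric", unit = "character"))

setValidity("MVMREstimate", function(object) {
  msg <- character(0)
  if (nrow(object@estimates) < 1) msg <- c(msg, "needs at least one exposure")
  if (object@nSnps < nrow(object@estimates) + 1 && nrow(object@estimates) >= 2)
    msg <- c(msg, "nSnps must be >= number of exposures + 1")
  if (length(msg)) msg else TRUE
})

#' ColocResult: posterior probabilities for the five colocalization hypotheses
#'
#' @slot pp named numeric of posteriors PP0..PP4 summing to one
#' @slot nVariants number of variants in the region
#' @slot priors list with p1, p2, p12
#' @slot decision TRUE iff PP4 strictly exceeds the decision threshold
#' @slot lead lead variant id for the conditional signal ("" for marginal)
#' @exportClass ColocResult
setClass("ColocResult",
  representation(pp = "numeric", nVariants = "numeric", priors = "list",
                 decision = "logical", lead = "character"))

setValidity("ColocResult", function(object) {
  msg <- character(0)
  if (length(object@pp) != 5) msg <- c(msg, "pp must have five entries")
  else {
    if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
      msg <- c(msg, "posteriors must be in [0,1]")
    if (abs(sum(object@pp) - 1) > 1e-9) msg <- c(msg, "posteriors must sum to 1")
  }
  if (object@nVariants < 1) msg <- c(msg, "nVariants must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats: %s (%s, %s), %d variants\n", object@trait,
              object@traitType, object@scale, nrow(object@records)))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix over %d variants\n", length(object@variants)))
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d individuals x %d variants\n",
              nrow(object@dosages), nrow(object@variants)))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet [%s]: %s -> %s, %d instruments\n", object@unit,
              object@exposureTrait, object@outcomeTrait, nrow(object@pairs)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] %s %s-effects: OR %.3f (95%% CI %.3f-%.3f), p = %.3g, n_snps = %d\n",
              object@unit, object@family, object@effects, object@or,
              exp(object@ciLow), exp(object@ciHigh), object@pvalue,
              as.integer(object@nSnps)))
  if (!is.na(object@qPvalue))
    cat(sprintf("  Cochran's Q = %.2f (df %d), p = %.3g\n", object@q,
                as.integer(object@qDf), object@qPvalue))
})

setMethod("show", "MVMREstimate", function(object) {
  cat(sprintf("MVMREstimate [%s]: %d exposures, %d instruments\n", object@unit,
              nrow(object@estimates), as.integer(object@nSnps)))
  print(object@estimates, digits = 3)
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult (%d variants): PP0-4 = %s; colocalized: %s\n",
              as.integer(object@nVariants),
              paste(sprintf("%.3f", object@pp), collapse = " "),
              object@decision))
})
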