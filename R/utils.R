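## Internal helpers shared across the pipeline.

#' @importFrom stats pchisq pnorm qnorm qchisq quantile rnorm runif rbinom sd
#'   var cor cov complete.cases ks.test plogis qlogis setNames coef glm
#'   binomial ave median
#' @importFrom utils read.table write.table head
#' @import methods
NULL

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complementAllele <- function(a) {
  out <- DNA_COMPLEMENT[toupper(a)]
  out[is.na(out)] <- NA_character_
  unname(out)
}

isPalindromic <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values
#' @return log(sum(exp(x))) computed without overflow
#' @keywords internal
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

variantId <- function(chrom, pos, a1, a2) {
  ## canonical id: allele pair sorted so the id is orientation-free
  amin <- pmin(toupper(a1), toupper(a2))
  amax <- pmax(toupper(a1), toupper(a2))
  paste(chrom, pos, amin, amax, sep = ":")
}

## two-sided normal p-value from an estimate and its SE, clamped away from
## zero so downstream distributional checks stay in (0, 1]
zPvalue <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), 1e-300)
}

pkgError <- function(class, msg, ...) {
  stop(structure(class = c(class, "drugTargetMR_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

pkgLog <- function(...) {
  message(sprintf("[drugTargetMR] %s", sprintf(...)))
}

## seed helper: derive a reproducible child seed below 2^31
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}
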