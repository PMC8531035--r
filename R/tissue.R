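## Tissue specificity from a normalized-expression (NX) matrix: the tau index
## and per-tissue z-scores. Expression is log2(x+1)-transformed before both
## metrics by default, following the tau-benchmarking literature; the raw
## variant is exposed for the scale-invariance property.

#' Tissue-specificity tau index
#'
#' With xhat_i = x_i / max(x) computed on the (by default log2(x+1)
#' transformed) expression values, tau = sum(1 - xhat_i) / (n - 1). tau is 0
#' for a uniformly expressed (housekeeping) gene and 1 for expression
#' confined to a single tissue.
#'
#' @param nx non-negative per-tissue normalized expression values (>= 2)
#' @param log2Transform apply log2(x+1) first (default TRUE)
#' @return tau in [0, 1]
#' @export
tauIndex <- function(nx, log2Transform = TRUE) {
  stopifnot(length(nx) >= 2, all(nx >= 0))
  if (max(nx) == 0)
    pkgError("undefined_tau_error", "all-zero expression profile")
  x <- if (log2Transform) log2(nx + 1) else nx
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

#' Per-tissue expression z-scores and top tissues
#'
#' z_i = (log2(x_i + 1) - mean) / sd across tissues. Top tissues are those
#' with z strictly above 1, ordered by decreasing z. A flat profile (zero sd)
#' yields all-zero z and no top tissue.
#'
#' @param nx non-negative per-tissue expression, named by tissue
#' @param log2Transform apply log2(x+1) first (default TRUE)
#' @return list with z (named numeric) and topTissues (character)
#' @export
tissueZ <- function(nx, log2Transform = TRUE) {
  stopifnot(length(nx) >= 2, all(nx >= 0))
  x <- if (log2Transform) log2(nx + 1) else nx
  s <- sd(x)
  z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  names(z) <- names(nx)
  top <- z[z > 1]
  list(z = z, topTissues = names(sort(top, decreasing = TRUE)))
}

#' Tissue-specificity scores for a gene x tissue expression matrix
#'
#' @param nxMatrix numeric matrix, rows = genes, columns = tissues
#' @param log2Transform apply log2(x+1) first (default TRUE)
#' @return data.frame with gene, tau, top_tissues (comma-separated, z > 1
#'   descending); genes with all-zero profiles get NA tau
#' @export
tissueSpecificity <- function(nxMatrix, log2Transform = TRUE) {
  nxMatrix <- as.matrix(nxMatrix)
  res <- lapply(rownames(nxMatrix), function(g) {
    nx <- nxMatrix[g, ]
    tau <- tryCatch(tauIndex(nx, log2Transform), error = function(e) NA_real_)
    tz <- tissueZ(nx, log2Transform)
    data.frame(gene = g, tau = tau,
               top_tissues = paste(tz$topTissues, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read a gene x tissue expression TSV
#'
#' @param path tab-delimited file: first column gene id, remaining columns
#'   tissue NX values
#' @return numeric matrix with gene rownames and tissue colnames
#' @export
readExpressionMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
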