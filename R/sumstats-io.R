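## Reading, QC and harmonization of GWAS summary statistics; LD estimation.

#' Default column-name mapping for summary-statistics tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names present in a delimited file. Override entries to read other dialects.
#'
#' @param ... named overrides, e.g. \code{beta = "Effect"}
#' @return named character vector mapping canonical -> file column names
#' @export
sumStatsDialect <- function(...) {
  d <- c(chrom = "chrom", pos = "pos", effect_allele = "effect_allele",
         other_allele = "other_allele", rsid = "rsid", beta = "beta",
         se = "se", pvalue = "pvalue", eaf = "eaf", n = "n")
  o <- c(...)
  d[names(o)] <- o
  d
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-delimited (optionally gzipped) table with a header, maps its
#' columns through \code{dialect}, and drops rows that violate the record
#' invariants (se > 0, eaf in (0,1), p in (0,1], distinct alleles, pos >= 1).
#' Dropped rows are counted and reported via a message; the count is attached
#' as the \code{"n_dropped"} attribute.
#'
#' @param path file path (plain or .gz)
#' @param trait trait label
#' @param traitType "quantitative" (per-SD effects) or "binary" (log-odds)
#' @param dialect column mapping from \code{\link{sumStatsDialect}}
#' @param sep field separator
#' @return a \linkS4class{SumStats}; attribute \code{n_dropped} counts removed rows
#' @export
readSumStats <- function(path, trait, traitType = c("quantitative", "binary"),
                         dialect = sumStatsDialect(), sep = "\t") {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) pkgError("format_error", paste("no such file:", path))
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) pkgError("format_error",
                                 paste("cannot parse", path, ":", conditionMessage(e))))
  if (nrow(tab) == 0) pkgError("format_error", paste("empty file:", path))
  required <- setdiff(names(sumStatsDialect()), "rsid")
  missing_cols <- required[!dialect[required] %in% names(tab)]
  if (length(missing_cols))
    pkgError("format_error",
             paste("missing required columns:",
                   paste(dialect[missing_cols], collapse = ", ")))
  rec <- data.frame(
    chrom = as.character(tab[[dialect[["chrom"]]]]),
    pos = as.integer(tab[[dialect[["pos"]]]]),
    effect_allele = toupper(as.character(tab[[dialect[["effect_allele"]]]])),
    other_allele = toupper(as.character(tab[[dialect[["other_allele"]]]])),
    beta = as.numeric(tab[[dialect[["beta"]]]]),
    se = as.numeric(tab[[dialect[["se"]]]]),
    pvalue = as.numeric(tab[[dialect[["pvalue"]]]]),
    eaf = as.numeric(tab[[dialect[["eaf"]]]]),
    n = as.numeric(tab[[dialect[["n"]]]]),
    stringsAsFactors = FALSE)
  if (dialect[["rsid"]] %in% names(tab))
    rec$rsid <- as.character(tab[[dialect[["rsid"]]]])
  ok <- complete.cases(rec[, REQUIRED_RECORD_COLS]) &
    rec$se > 0 & rec$eaf > 0 & rec$eaf < 1 &
    rec$pvalue > 0 & rec$pvalue <= 1 & rec$pos >= 1 &
    rec$effect_allele != rec$other_allele
  ids <- variantId(rec$chrom, rec$pos, rec$effect_allele, rec$other_allele)
  ok <- ok & !duplicated(ids)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    pkgLog("readSumStats(%s): dropped %d of %d rows failing record invariants",
           trait, n_dropped, nrow(rec))
  out <- SumStats(rec[ok, , drop = FALSE], trait = trait, traitType = traitType)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Quality-control a reference panel
#'
#' Retains exactly the variants passing the tiered frequency/quality rules:
#' MAF >= 0.001 and imputation info >= 0.3, and not (MAF < 0.005 and genotype
#' probability < 0.9), not (MAF < 0.01 and gprob < 0.8), not (MAF < 0.03 and
#' gprob < 0.6). An empty panel is allowed.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @return the filtered \linkS4class{ReferencePanel}; attribute
#'   \code{n_dropped} counts removed variants
#' @export
qcReference <- function(panel) {
  keep <- panel@maf >= 0.001 & panel@info >= 0.3 &
    !(panel@maf < 0.005 & panel@gprob < 0.9) &
    !(panel@maf < 0.01 & panel@gprob < 0.8) &
    !(panel@maf < 0.03 & panel@gprob < 0.6)
  out <- new("ReferencePanel",
             dosages = panel@dosages[, keep, drop = FALSE],
             variants = panel@variants[keep, , drop = FALSE],
             maf = panel@maf[keep], info = panel@info[keep],
             gprob = panel@gprob[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Estimate a signed LD matrix from panel dosages
#'
#' Pearson correlation of effect-allele dosage columns, signed relative to the
#' effect alleles of the panel. Missing dosages are mean-imputed per variant.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param subset optional canonical variant ids restricting (and ordering) the
#'   output; defaults to all panel variants
#' @return an \linkS4class{LDMatrix}
#' @export
computeLD <- function(panel, subset = NULL) {
  ids <- colnames(panel@dosages)
  if (is.null(subset)) subset <- ids
  missing_ids <- setdiff(subset, ids)
  if (length(missing_ids))
    pkgError("format_error", paste("variants absent from panel:",
                                   paste(head(missing_ids, 5), collapse = ", ")))
  x <- panel@dosages[, subset, drop = FALSE]
  if (nrow(x) < 2) pkgError("format_error", "need >= 2 individuals")
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    pkgError("degenerate_variant_error",
             paste("zero-variance dosage for:",
                   paste(subset[sds == 0], collapse = ", ")))
  r <- cor(x)
  LDMatrix(r, subset)
}

#' Read a precomputed LD matrix from a square TSV
#'
#' @param path square tab-delimited file with a variant-id header and matching
#'   row order
#' @return an \linkS4class{LDMatrix}
#' @export
readLDMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  LDMatrix(as.matrix(tab), colnames(tab))
}

#' Harmonize outcome effects to the exposure's effect alleles
#'
#' Matches variants across the two datasets by (chrom, pos, allele set) —
#' robust to rsid drift across consortium releases — and aligns the outcome
#' betas to the exposure effect alleles: sign flip and eaf complement when the
#' allele labels are swapped; strand flips (A<->T, C<->G complements)
#' reconciled. Palindromic (A/T or C/G) variants whose MAF is at or above
#' \code{palindromeMAF} in either dataset are removed because strand cannot be
#' inferred; below the threshold they are aligned by allele frequency (or all
#' removed when \code{dropAllPalindromes = TRUE}). Irreconcilable allele sets
#' are dropped with a logged reason.
#'
#' @param exposure,outcome \linkS4class{SumStats} objects
#' @param palindromeMAF frequency threshold above which palindromic variants
#'   are removed (default 0.3)
#' @param dropAllPalindromes remove every palindromic variant regardless of MAF
#' @return data.frame of harmonized pairs with columns variant, chrom, pos,
#'   effect_allele, other_allele, bx, sx, px, eaf, nx, by, sy, py, eafy, ny;
#'   attribute \code{drops} is a data.frame of dropped variants and reasons
#' @export
harmonize <- function(exposure, outcome, palindromeMAF = 0.3,
                      dropAllPalindromes = FALSE) {
  ex <- exposure@records
  oy <- outcome@records
  ex$id <- variantId(ex$chrom, ex$pos, ex$effect_allele, ex$other_allele)
  oy$id_raw <- variantId(oy$chrom, oy$pos, oy$effect_allele, oy$other_allele)
  ## also index the outcome under the strand-complement id so flipped records match
  oy$id_comp <- variantId(oy$chrom, oy$pos,
                          complementAllele(oy$effect_allele),
                          complementAllele(oy$other_allele))
  drops <- list()
  rows <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    j <- match(e$id, oy$id_raw)
    flipped_strand <- FALSE
    if (is.na(j)) {
      j <- match(e$id, oy$id_comp)
      flipped_strand <- TRUE
    }
    if (is.na(j)) next  # variant absent from outcome: not a harmonization drop
    o <- oy[j, ]
    o_ea <- o$effect_allele
    o_oa <- o$other_allele
    if (flipped_strand) {
      o_ea <- complementAllele(o_ea)
      o_oa <- complementAllele(o_oa)
    }
    pal <- isPalindromic(e$effect_allele, e$other_allele)
    if (pal) {
      maf_e <- min(e$eaf, 1 - e$eaf)
      maf_o <- min(o$eaf, 1 - o$eaf)
      if (dropAllPalindromes || maf_e >= palindromeMAF || maf_o >= palindromeMAF) {
        drops[[length(drops) + 1]] <- data.frame(
          variant = e$id, reason = "palindromic", stringsAsFactors = FALSE)
        next
      }
      ## infer orientation from frequency: effect alleles agree iff eafs are on
      ## the same side of 0.5
      same <- (e$eaf < 0.5) == (o$eaf < 0.5)
      by <- if (same) o$beta else -o$beta
      eafy <- if (same) o$eaf else 1 - o$eaf
    } else if (o_ea == e$effect_allele && o_oa == e$other_allele) {
      by <- o$beta
      eafy <- o$eaf
    } else if (o_ea == e$other_allele && o_oa == e$effect_allele) {
      by <- -o$beta
      eafy <- 1 - o$eaf
    } else {
      drops[[length(drops) + 1]] <- data.frame(
        variant = e$id, reason = "irreconcilable_alleles",
        stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(
      variant = e$id, chrom = e$chrom, pos = e$pos,
      effect_allele = e$effect_allele, other_allele = e$other_allele,
      bx = e$beta, sx = e$se, px = e$pvalue, eaf = e$eaf, nx = e$n,
      by = by, sy = o$se, py = o$pvalue, eafy = eafy, ny = o$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(variant = character(0), chrom = character(0),
                      pos = integer(0), effect_allele = character(0),
                      other_allele = character(0), bx = numeric(0),
                      sx = numeric(0), px = numeric(0), eaf = numeric(0),
                      nx = numeric(0), by = numeric(0), sy = numeric(0),
                      py = numeric(0), eafy = numeric(0), ny = numeric(0))
  rownames(out) <- NULL
  dropdf <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant = character(0), reason = character(0))
  if (nrow(dropdf) > 0)
    pkgLog("harmonize: dropped %d variants (%s)", nrow(dropdf),
           paste(sprintf("%s: %d", names(table(dropdf$reason)),
                         table(dropdf$reason)), collapse = ", "))
  attr(out, "drops") <- dropdf
  out
}

#' Write a TSV plus a JSON run manifest
#'
#' All pipeline stage outputs are flat TSVs; the manifest records inputs,
#' parameters, drop counts and the seed so any stage can be re-run identically.
#'
#' @param x data.frame to write
#' @param path output TSV path
#' @param manifest named list recorded alongside as \code{<path>.manifest.json}
#' @return invisibly, the TSV path
#' @export
writeStage <- function(x, path, manifest = list()) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(manifest))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
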