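## Instrument selection: significance/MAF filters, greedy LD clumping, and
## druggable-gene region mapping.

#' Build a gene-annotation GRanges from a BED-like TSV
#'
#' Expects columns chrom, start, end, gene_id, symbol, druggable (logical or
#' 0/1). Coordinates are 1-based inclusive (GRCh37), matching the locus
#' notation used throughout the package.
#'
#' @param path tab-delimited annotation file with header
#' @return a \code{GRanges} with mcols gene_id, symbol, druggable
#' @export
readGeneAnnotation <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "symbol", "druggable")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    pkgError("format_error", paste("annotation missing columns:",
                                   paste(missing_cols, collapse = ", ")))
  geneRegions(tab$chrom, tab$start, tab$end, tab$gene_id, tab$symbol,
              as.logical(tab$druggable))
}

#' Construct gene regions as a GRanges
#'
#' @param chrom,start,end 1-based inclusive GRCh37 coordinates
#' @param gene_id,symbol identifiers
#' @param druggable logical flag per gene
#' @return a \code{GRanges} with mcols gene_id, symbol, druggable
#' @export
geneRegions <- function(chrom, start, end, gene_id, symbol,
                        druggable = rep(TRUE, length(chrom))) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)))
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$symbol <- as.character(symbol)
  S4Vectors::mcols(gr)$druggable <- as.logical(druggable)
  gr
}

#' Greedy LD clumping of candidate variants
#'
#' Scans candidates by ascending p-value (ties broken by chromosome then
#' position, so the result is invariant to input order) and keeps a variant
#' iff its squared correlation with every already-kept variant is strictly
#' below \code{r2Max}.
#'
#' @param candidates data.frame with columns variant, pvalue, chrom, pos
#' @param ld \linkS4class{LDMatrix} covering the candidates
#' @param r2Max clumping threshold on r-squared (default 0.4)
#' @return character vector of retained variant ids (in scan order)
#' @export
ldClump <- function(candidates, ld, r2Max = 0.4) {
  if (nrow(candidates) == 0) return(character(0))
  missing_ids <- setdiff(candidates$variant, ld@variants)
  if (length(missing_ids))
    pkgError("format_error", paste("candidates not in LD matrix:",
                                   paste(head(missing_ids, 5), collapse = ", ")))
  ord <- order(candidates$pvalue, candidates$chrom, candidates$pos)
  cand <- candidates$variant[ord]
  r2 <- ld@r[cand, cand, drop = FALSE]^2
  kept <- character(0)
  for (v in cand) {
    if (length(kept) == 0 || all(r2[v, kept] < r2Max)) kept <- c(kept, v)
  }
  kept
}

## shared filtering + clumping core for genome-wide and cis selection
selectInstruments <- function(pairs, ld, pMax, mafMin, r2Max, unit,
                              exposureTrait, outcomeTrait) {
  maf <- pmin(pairs$eaf, 1 - pairs$eaf)
  keep <- pairs$px <= pMax & maf > mafMin
  cand <- pairs[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    pkgError("empty_instrument_error",
             sprintf("no instruments survive selection for unit '%s'", unit),
             stage = unit)
  kept <- ldClump(data.frame(variant = cand$variant, pvalue = cand$px,
                             chrom = cand$chrom, pos = cand$pos,
                             stringsAsFactors = FALSE),
                  ld, r2Max = r2Max)
  cand <- cand[match(kept, cand$variant), , drop = FALSE]
  sub <- LDMatrix(ld@r[kept, kept, drop = FALSE], kept)
  InstrumentSet(cand, sub, unit = unit, exposureTrait = exposureTrait,
                outcomeTrait = outcomeTrait)
}

#' Select genome-wide instruments
#'
#' Applies the exposure significance threshold (default p <= 1e-6), the
#' MAF > 0.01 filter, and greedy LD clumping at r-squared < 0.4 to a
#' harmonized exposure/outcome pair table.
#'
#' @param harmonized harmonized pair table from \code{\link{harmonize}}
#' @param ld \linkS4class{LDMatrix} covering the candidate variants
#' @param pMax exposure p-value threshold (default 1e-6)
#' @param mafMin strict lower bound on MAF (default 0.01)
#' @param r2Max clumping threshold (default 0.4)
#' @param exposureTrait,outcomeTrait labels recorded on the result
#' @return an \linkS4class{InstrumentSet} labelled "genome-wide"
#' @export
selectGenomewide <- function(harmonized, ld, pMax = 1e-6, mafMin = 0.01,
                             r2Max = 0.4, exposureTrait = "exposure",
                             outcomeTrait = "outcome") {
  selectInstruments(harmonized, ld, pMax, mafMin, r2Max, "genome-wide",
                    exposureTrait, outcomeTrait)
}

#' Select cis instruments for one gene region
#'
#' Restricts the harmonized pairs to the gene body plus \code{flank} bp on
#' each side (inclusive window on 1-based GRCh37 coordinates) and then applies
#' the cis significance threshold (default p <= 1e-4), the MAF filter and
#' greedy clumping, as in \code{\link{selectGenomewide}}.
#'
#' @param harmonized harmonized pair table from \code{\link{harmonize}}
#' @param gene a single-range \code{GRanges} row from
#'   \code{\link{geneRegions}}
#' @param ld \linkS4class{LDMatrix} covering the candidate variants
#' @param pMax cis p-value threshold (default 1e-4)
#' @param mafMin strict lower bound on MAF (default 0.01)
#' @param r2Max clumping threshold (default 0.4)
#' @param flank window extension in bp (default 50000)
#' @param exposureTrait,outcomeTrait labels recorded on the result
#' @return an \linkS4class{InstrumentSet} labelled with the gene symbol
#' @export
selectCis <- function(harmonized, gene, ld, pMax = 1e-4, mafMin = 0.01,
                      r2Max = 0.4, flank = 50000,
                      exposureTrait = "exposure", outcomeTrait = "outcome") {
  stopifnot(length(gene) == 1)
  lo <- GenomicRanges::start(gene) - flank
  hi <- GenomicRanges::end(gene) + flank
  chr <- as.character(GenomicRanges::seqnames(gene))
  sym <- S4Vectors::mcols(gene)$symbol
  inwin <- harmonized$chrom == chr & harmonized$pos >= lo & harmonized$pos <= hi
  sub <- harmonized[inwin, , drop = FALSE]
  if (nrow(sub) == 0)
    pkgError("empty_instrument_error",
             sprintf("no variants in window for gene '%s'", sym), stage = sym)
  selectInstruments(sub, ld, pMax, mafMin, r2Max, sym,
                    exposureTrait, outcomeTrait)
}

#' Map selected variants to overlapping druggable genes
#'
#' A gene is reported iff at least one selected variant lies within
#' [start - flank, end + flank] (inclusive). Each mapped variant carries its
#' base-pair distance to the gene (0 inside the gene body, else distance to
#' the nearest gene edge) and a distance rank among the genes that variant
#' overlaps (rank 1 = closest).
#'
#' @param selected data.frame with columns variant, chrom, pos
#' @param genes \code{GRanges} from \code{\link{geneRegions}}
#' @param flank window extension in bp (default 50000)
#' @param druggableOnly restrict to genes flagged druggable (default TRUE)
#' @return data.frame with gene_id, symbol, variant, distance_bp, distance_rank
#' @export
mapDruggableGenes <- function(selected, genes, flank = 50000,
                              druggableOnly = TRUE) {
  if (druggableOnly) genes <- genes[S4Vectors::mcols(genes)$druggable]
  if (length(genes) == 0 || nrow(selected) == 0)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      variant = character(0), distance_bp = integer(0),
                      distance_rank = integer(0)))
  vr <- GenomicRanges::GRanges(selected$chrom,
                               IRanges::IRanges(selected$pos, selected$pos))
  win <- GenomicRanges::resize(genes, GenomicRanges::width(genes) + 2 * flank,
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(vr, win)
  if (length(hits) == 0)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      variant = character(0), distance_bp = integer(0),
                      distance_rank = integer(0)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- selected$pos[qi]
  gstart <- GenomicRanges::start(genes)[si]
  gend <- GenomicRanges::end(genes)[si]
  dist <- ifelse(pos >= gstart & pos <= gend, 0L,
                 pmin(abs(pos - gstart), abs(pos - gend)))
  out <- data.frame(gene_id = S4Vectors::mcols(genes)$gene_id[si],
                    symbol = S4Vectors::mcols(genes)$symbol[si],
                    variant = selected$variant[qi],
                    distance_bp = as.integer(dist),
                    stringsAsFactors = FALSE)
  ## rank genes per variant by ascending distance
  out$distance_rank <- stats::ave(out$distance_bp, out$variant,
                                  FUN = function(d) rank(d, ties.method = "first"))
  out <- out[order(out$symbol, out$distance_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid-search calibration of the cis-MR selection parameters
#'
#' Runs cis instrument selection plus the selected MR model over a grid of
#' (flank window, r-squared threshold) cells for a set of positive-control
#' genes with known expected effect directions, and reports per cell the
#' fraction of controls recovering the expected direction, the mean |beta|/SE,
#' and the instrument counts. Cells with no surviving instruments are recorded
#' as missing, not fatal. Consistency is reported, never optimized
#' automatically.
#'
#' @param harmonized harmonized pair table from \code{\link{harmonize}}
#' @param controls data.frame with columns symbol, expected_direction
#'   ("positive"/"negative" slope sign)
#' @param genes \code{GRanges} annotation covering the control symbols
#' @param ld \linkS4class{LDMatrix}
#' @param windows bp flank values to scan
#' @param r2s r-squared thresholds to scan
#' @param pMax cis p-value threshold
#' @return data.frame with one row per grid cell:
#'   flank, r2_max, n_controls, fraction_correct, mean_abs_z, mean_n_snps
#' @export
gridSearchCalibration <- function(harmonized, controls, genes, ld,
                                  windows = c(25000, 50000, 100000),
                                  r2s = c(0.2, 0.4, 0.6), pMax = 1e-4) {
  stopifnot(nrow(controls) >= 1, length(windows) >= 1, length(r2s) >= 1)
  cells <- expand.grid(flank = windows, r2_max = r2s)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    fl <- cells$flank[k]; r2 <- cells$r2_max[k]
    dirs <- zs <- ns <- rep(NA_real_, nrow(controls))
    for (i in seq_len(nrow(controls))) {
      g <- genes[S4Vectors::mcols(genes)$symbol == controls$symbol[i]]
      fit <- tryCatch({
        instr <- selectCis(harmonized, g, ld, pMax = pMax, r2Max = r2,
                           flank = fl)
        selectModel(instr)
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        dirs[i] <- sign(fit@beta) == ifelse(
          controls$expected_direction[i] == "positive", 1, -1)
        zs[i] <- abs(fit@beta / fit@se)
        ns[i] <- fit@nSnps
      }
    }
    data.frame(flank = fl, r2_max = r2, n_controls = sum(!is.na(dirs)),
               fraction_correct = mean(dirs, na.rm = TRUE),
               mean_abs_z = mean(zs, na.rm = TRUE),
               mean_n_snps = mean(ns, na.rm = TRUE))
  })
  do.call(rbind, res)
}
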