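## Target prioritization: therapeutic orientation of estimates, replication
## concordance, the KS multiplicity check, OR quartile summaries, drug
## annotation matching, and the region-based phenome-wide scan.

#' Orient an MR estimate toward the therapeutic direction
#'
#' Drug effects are coded toward the canonical therapeutic direction: lower
#' LDL-C and triglycerides, higher HDL-C. The therapeutic OR is therefore the
#' reciprocal of the per-SD-increase OR for LDL-C and TG, and the OR itself
#' for HDL-C; CI bounds are transformed consistently (reciprocal swaps them).
#' An estimate is beneficial iff the therapeutic OR is below 1.
#'
#' @param est an \linkS4class{MREstimate} on the per-SD-increase scale
#' @param lipid one of "LDL-C", "HDL-C", "TG"
#' @param alpha significance level for the significance flag (default 0.05)
#' @return data.frame with unit, lipid, or, ci_low, ci_high, pvalue,
#'   therapeutic_or, therapeutic_ci_low, therapeutic_ci_high, beneficial,
#'   significant
#' @export
orientEstimate <- function(est, lipid = c("LDL-C", "HDL-C", "TG"),
                           alpha = 0.05) {
  lipid <- match.arg(lipid)
  stopifnot(is.finite(est@or))
  flip <- lipid %in% c("LDL-C", "TG")
  th_or <- if (flip) 1 / est@or else est@or
  th_lo <- if (flip) exp(-est@ciHigh) else exp(est@ciLow)
  th_hi <- if (flip) exp(-est@ciLow) else exp(est@ciHigh)
  data.frame(unit = est@unit, lipid = lipid, or = est@or,
             ci_low = exp(est@ciLow), ci_high = exp(est@ciHigh),
             pvalue = est@pvalue, therapeutic_or = th_or,
             therapeutic_ci_low = th_lo, therapeutic_ci_high = th_hi,
             beneficial = th_or < 1, significant = est@pvalue < alpha,
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' Two-sided one-sample KS test of the discovery p-values against the
#' continuous Uniform(0,1) expected under the global null; used to check that
#' the body of discovery findings is not explained by multiple testing.
#'
#' @param pvalues numeric vector in (0,1], length >= 5
#' @return list with statistic (D) and pvalue
#' @export
ksUniformity <- function(pvalues) {
  if (length(pvalues) < 5)
    pkgError("insufficient_sample_error", "need at least 5 p-values")
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  kt <- suppressWarnings(ks.test(pvalues, "punif"))
  list(statistic = unname(kt$statistic), pvalue = kt$p.value)
}

#' Replication concordance between discovery and replication estimates
#'
#' Units are matched by (unit, lipid). Among replication estimates with
#' p < alpha, an estimate is concordant iff its therapeutic OR lies on the
#' same side of 1 as the discovery estimate. The headline fraction is
#' n_concordant / n_replication_significant.
#'
#' @param discovery,replication data.frames of oriented estimates from
#'   \code{\link{orientEstimate}} (row-bound)
#' @param alpha replication significance level (default 0.05)
#' @return list with counts, fraction_concordant, and the per-unit table
#' @export
replicationConcordance <- function(discovery, replication, alpha = 0.05) {
  key <- function(d) paste(d$unit, d$lipid, sep = "|")
  shared <- intersect(key(discovery), key(replication))
  if (length(shared) == 0)
    pkgError("empty_overlap_error", "no overlapping (unit, lipid) pairs")
  d <- discovery[match(shared, key(discovery)), , drop = FALSE]
  r <- replication[match(shared, key(replication)), , drop = FALSE]
  sig <- r$pvalue < alpha
  concord <- sig & (sign(log(r$therapeutic_or)) == sign(log(d$therapeutic_or)))
  per_unit <- data.frame(unit = d$unit, lipid = d$lipid,
                         discovery_or = d$therapeutic_or,
                         replication_or = r$therapeutic_or,
                         replication_p = r$pvalue,
                         replication_significant = sig,
                         concordant = concord, stringsAsFactors = FALSE)
  list(n_discovery_significant = sum(d$significant),
       n_replication_tested = length(shared),
       n_replication_significant = sum(sig),
       n_concordant = sum(concord),
       fraction_concordant = if (sum(sig) > 0) sum(concord) / sum(sig)
       else NA_real_,
       per_unit = per_unit)
}

#' First and third quartiles of significant ORs per lipid
#'
#' ORs are recoded to the per-SD-increase direction and summarized by the
#' linear-interpolation quantile definition. Groups with fewer than four
#' significant estimates are skipped with a log message.
#'
#' @param oriented data.frame of oriented estimates (must carry lipid, or,
#'   significant)
#' @return data.frame with lipid, n, q1, q3
#' @export
summarizeQuartiles <- function(oriented) {
  out <- lapply(split(oriented, oriented$lipid), function(g) {
    g <- g[g$significant, , drop = FALSE]
    if (nrow(g) < 4) {
      pkgLog("summarizeQuartiles: skipping %s (only %d significant estimates)",
             g$lipid[1] %||% "?", nrow(g))
      return(NULL)
    }
    q <- quantile(g$or, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(lipid = g$lipid[1], n = nrow(g), q1 = q[1], q3 = q[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(lipid = character(0), n = integer(0), q1 = numeric(0),
                      q3 = numeric(0))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Match drug-annotation free text against lipid keyword stems
#'
#' Case-insensitive stem matching (default stems: lipo, lipid, ldl, hdl,
#' cholest, triglyceride, each understood with a trailing wildcard). Matching
#' is either substring (default, so "hyperlipidaemia" matches lipid*) or
#' token-prefix on whitespace/punctuation-delimited tokens. Adverse-event
#' records that affected zero study participants are excluded.
#'
#' @param annotations data.frame with columns gene, source, category
#'   ("indication", "outcome" or "adverse event"), text, and optionally
#'   affected (participant count, used for adverse events)
#' @param keywords keyword stems (without wildcard)
#' @param mode "substring" or "token_prefix"
#' @return data.frame with gene, source, category, keyword, matched_text
#' @export
matchAnnotations <- function(annotations,
                             keywords = c("lipo", "lipid", "ldl", "hdl",
                                          "cholest", "triglyceride"),
                             mode = c("substring", "token_prefix")) {
  mode <- match.arg(mode)
  if ("affected" %in% names(annotations)) {
    ae <- annotations$category == "adverse event"
    annotations <- annotations[!(ae & annotations$affected <= 0), ,
                               drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    txt <- tolower(annotations$text[i])
    toks <- strsplit(txt, "[^a-z0-9]+")[[1]]
    for (kw in keywords) {
      hit <- if (mode == "substring") grepl(kw, txt, fixed = TRUE)
      else any(startsWith(toks, kw))
      if (hit)
        rows[[length(rows) + 1]] <- data.frame(
          gene = annotations$gene[i], source = annotations$source[i],
          category = annotations$category[i], keyword = kw,
          matched_text = annotations$text[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), source = character(0),
                      category = character(0), keyword = character(0),
                      matched_text = character(0))
  out
}

#' Region-based phenome-wide scan
#'
#' For each gene region (body plus \code{flank} bp, inclusive window) and each
#' phenotype, reports the minimum association p-value among region variants
#' after removing palindromic variants with MAF >= \code{palindromeMAF}, and
#' flags it when below the genome-wide threshold. Phenotypes with no region
#' variants are recorded as missing (NA).
#'
#' @param genes \code{GRanges} from \code{\link{geneRegions}}
#' @param phenotypes named list of \linkS4class{SumStats}
#' @param flank window extension in bp (default 50000)
#' @param pGw genome-wide significance threshold (default 5e-8)
#' @param palindromeMAF palindrome removal threshold (default 0.3)
#' @return data.frame with gene, phenotype, n_variants, min_p, significant
#' @export
phewasScan <- function(genes, phenotypes, flank = 50000, pGw = 5e-8,
                       palindromeMAF = 0.3) {
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    chr <- as.character(GenomicRanges::seqnames(g))
    lo <- GenomicRanges::start(g) - flank
    hi <- GenomicRanges::end(g) + flank
    for (ph in names(phenotypes)) {
      rec <- phenotypes[[ph]]@records
      pal <- isPalindromic(rec$effect_allele, rec$other_allele) &
        pmin(rec$eaf, 1 - rec$eaf) >= palindromeMAF
      inwin <- rec$chrom == chr & rec$pos >= lo & rec$pos <= hi & !pal
      nv <- sum(inwin)
      minp <- if (nv > 0) min(rec$pvalue[inwin]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        gene = S4Vectors::mcols(g)$symbol, phenotype = ph, n_variants = nv,
        min_p = minp, significant = !is.na(minp) && minp < pGw,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
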