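## Shared helpers: quick construction of instrument sets and summary tables.

## minimal variant table for n hand-built variants
hVariants <- function(n, chrom = "1", start = 100, step = 100) {
  data.frame(chrom = chrom, pos = start + (seq_len(n) - 1) * step,
             effect_allele = rep(c("A", "C", "T", "G"), length.out = n),
             other_allele = rep(c("G", "T", "C", "A"), length.out = n),
             stringsAsFactors = FALSE)
}

hIds <- function(vt) with(vt, drugTargetMR:::variantId(chrom, pos,
                                                       effect_allele,
                                                       other_allele))

## build an InstrumentSet from raw vectors (identity LD by default)
makeInstr <- function(bx, sx, by, sy, R = NULL, px = NULL, eaf = NULL,
                      unit = "test") {
  n <- length(bx)
  vt <- hVariants(n)
  ids <- hIds(vt)
  if (is.null(R)) R <- diag(n)
  if (is.null(px)) px <- rep(1e-8, n)
  if (is.null(eaf)) eaf <- rep(0.3, n)
  pairs <- data.frame(variant = ids, chrom = vt$chrom, pos = vt$pos,
                      bx = bx, sx = sx, by = by, sy = sy, px = px, eaf = eaf,
                      stringsAsFactors = FALSE)
  InstrumentSet(pairs, LDMatrix(R, ids), unit = unit)
}

## closed-form inverse-variance-weighted oracle (identity LD, first-order
## weights bx^2/sy^2); independent of the GLS implementation
ivwOracle <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  ratio <- by / bx
  slope <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(slope = slope, se = se)
}

## build an InstrumentSet straight from simulated SumStats (the generator
## emits both traits on identical variant codings, so alignment is direct)
instrFromSim <- function(gwas, ld, exposure = 1, pMax = 1, unit = "sim") {
  ex <- records(gwas$exposures[[exposure]])
  oy <- records(gwas$outcome)
  ids <- variantIds(gwas$exposures[[exposure]])
  keep <- ex$pvalue <= pMax
  pairs <- data.frame(variant = ids, chrom = ex$chrom, pos = ex$pos,
                      bx = ex$beta, sx = ex$se, by = oy$beta, sy = oy$se,
                      px = ex$pvalue, eaf = ex$eaf,
                      stringsAsFactors = FALSE)[keep, ]
  InstrumentSet(pairs, LDMatrix(ld@r[keep, keep, drop = FALSE],
                                ids[keep]), unit = unit)
}

## write a SumStats-shaped table to a temp TSV, returning the path
writeSumStatsTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## 3-variant well-formed summary-statistics table
hSumTab <- function() {
  cbind(hVariants(3),
        data.frame(beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.03, 0.01),
                   pvalue = c(1e-8, 1e-4, 0.2), eaf = c(0.2, 0.4, 0.45),
                   n = rep(10000, 3)))
}

## MREstimate from a printed OR and 95% CI
mkEstimate <- function(or, ci, p = 0.01, unit = "G") {
  beta <- log(or)
  se <- (log(ci[2]) - log(ci[1])) / (2 * qnorm(0.975))
  new("MREstimate", beta = beta, se = se, ciLow = log(ci[1]),
      ciHigh = log(ci[2]), pvalue = p, or = or, intercept = NA_real_,
      interceptSE = NA_real_, q = 1, qDf = 4, qPvalue = 0.9, nSnps = 5,
      family = "ivw", effects = "fixed", unit = unit)
}

## brute-force enumeration oracle over causal-variant assignments
colocEnumOracle <- function(bfx, bfy, priors) {
  p <- length(bfx)
  h0 <- 1
  h1 <- priors$p1 * sum(bfx)
  h2 <- priors$p2 * sum(bfy)
  h3 <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) h3 <- h3 + priors$p1 * priors$p2 * bfx[i] * bfy[j]
  }
  h4 <- priors$p12 * sum(bfx * bfy)
  tot <- h0 + h1 + h2 + h3 + h4
  c(h0, h1, h2, h3, h4) / tot
}
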