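## End-to-end orchestration over a flat-file fixture directory, plus the
## fixture generator itself. Every stage writes a TSV and a JSON manifest so
## identical configs reproduce identical outputs.

LIPID_SLUGS <- c("LDL-C" = "ldl", "HDL-C" = "hdl", "TG" = "tg")

#' Generate a self-contained fixture directory
#'
#' Writes synthetic summary statistics (three correlated lipid exposures and
#' a binary outcome, discovery and replication), a precomputed LD matrix,
#' gene annotation with druggable flags, a gene x tissue expression matrix,
#' drug-annotation text records, two region phenotypes for the phenome scan,
#' and a JSON run config — everything the pipeline readers consume, sized to
#' run end-to-end in well under a minute.
#'
#' The constructed truth: four independent 20-variant LD blocks on
#' chromosome 1, separated by 200 kb. Blocks 1-3 carry the LDL-C, HDL-C and
#' TG causal variants respectively; block 4 is causal-free. GENE1 (LDL
#' block) is a druggable positive control that replicates and colocalizes;
#' GENE3 (TG block) has its outcome signal sign-reversed in the replication
#' draw (designed discordant); GENE4 (null block) exercises the
#' no-instruments path. Expression patterns: GENE1 one-hot liver, GENE2
#' graded, GENE3 uniform, GENE4 graded.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return invisibly, \code{dir}; side effect: fixture files
#' @export
makeFixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- 80
  blocks <- list(1:20, 21:40, 41:60, 61:80)
  B <- matrix(0, m, 3)
  set.seed(childSeed(seed, 20))
  for (j in 1:3) {                      # block 4 stays causal-free (null gene)
    idx <- sample(blocks[[j]], 8)
    B[idx, j] <- rnorm(8, 0, sqrt(0.15 / 8)) + 0.08 * sign(rnorm(8))
  }
  cfg <- simConfig(nVariants = m, nRef = 2000, rho = 0.8, blockSize = 20,
                   theta = c(0.43, -0.09, 0.09), caseFraction = 0.33,
                   nExposure = 188577, nOutcome = 184305, seed = seed)
  cfg$causalEffects <- B
  sim <- simulatePanel(cfg)
  disc <- simulateGwas(sim, cfg, mode = "summary", seed = childSeed(seed, 21))
  repCfg <- cfg
  repCfg$nExposure <- 33029
  repCfg$nOutcome <- 296525
  repCfg$caseFraction <- 0.1165
  ## discordant gene: direct outcome effects reverse the block-3 outcome
  ## signal in the replication truth, flipping the TG-weighted slope there
  liab <- drop(B %*% cfg$theta)
  repCfg$pleiotropy <- rep(0, m)
  repCfg$pleiotropy[blocks[[3]]] <- -2 * liab[blocks[[3]]]
  repl <- simulateGwas(sim, repCfg, mode = "summary",
                       seed = childSeed(seed, 22))
  for (j in 1:3) {
    slug <- LIPID_SLUGS[j]
    writeStage(disc$exposures[[j]]@records,
               file.path(dir, sprintf("exposure_discovery_%s.tsv", slug)))
    writeStage(repl$exposures[[j]]@records,
               file.path(dir, sprintf("exposure_replication_%s.tsv", slug)))
  }
  writeStage(disc$outcome@records, file.path(dir, "outcome_discovery.tsv"))
  writeStage(repl$outcome@records, file.path(dir, "outcome_replication.tsv"))
  ldtab <- as.data.frame(sim$ld@r)
  names(ldtab) <- sim$ld@variants
  writeStage(ldtab, file.path(dir, "ld.tsv"))
  pos <- sim$panel@variants$pos
  genes <- data.frame(
    chrom = "1",
    start = c(pos[4], pos[24], pos[44], pos[64]),
    end = c(pos[17], pos[37], pos[57], pos[77]),
    gene_id = paste0("ENSG0000000000", 1:4),
    symbol = paste0("GENE", 1:4),
    druggable = c(TRUE, TRUE, TRUE, TRUE))
  writeStage(genes, file.path(dir, "genes.tsv"))
  tissues <- c("liver", "kidney", "brain", "adipose", "blood")
  expr <- simulateExpression(4, tissues,
                             patterns = c("one-hot", "graded", "uniform",
                                          "graded"),
                             seed = childSeed(seed, 23))
  rownames(expr) <- genes$symbol
  expr["GENE1", ] <- c(50, 0, 0, 0, 0)   # planted liver-specific control
  writeStage(cbind(data.frame(gene = rownames(expr)), as.data.frame(expr)),
             file.path(dir, "expression.tsv"))
  ann <- data.frame(
    gene = c("GENE1", "GENE1", "GENE2", "GENE3", "GENE4"),
    source = c("formulary", "registry", "registry", "registry", "formulary"),
    category = c("indication", "adverse event", "outcome", "adverse event",
                 "indication"),
    text = c("Hypercholesterolaemia and mixed dyslipidaemia",
             "hyperlipidaemia reported in treatment arm",
             "Change in LDL cholesterol from baseline",
             "hyperlipidaemia", "hypertension"),
    affected = c(NA, 3L, NA, 0L, NA))
  writeStage(ann, file.path(dir, "drug_annotations.tsv"))
  ## two phenome-scan phenotypes: one with a planted signal in GENE1's region
  set.seed(childSeed(seed, 24))
  vt <- sim$panel@variants
  mkpheno <- function(pv) {
    b <- rnorm(m, 0, 0.01)
    se <- rep(0.01, m)
    cbind(vt, data.frame(beta = b, se = se, pvalue = pv,
                         eaf = sim$maf, n = 100000))
  }
  ph1 <- mkpheno(runif(m))
  ph1$pvalue[10] <- 1e-10
  ph2 <- mkpheno(runif(m))
  writeStage(ph1, file.path(dir, "phenotype_pheno1.tsv"))
  writeStage(ph2, file.path(dir, "phenotype_pheno2.tsv"))
  jsonlite::write_json(
    list(seed = seed, p_max_genomewide = 1e-6, p_max_cis = 1e-4,
         maf_min = 0.01, r2_max = 0.4, flank_bp = 50000, q_alpha = 0.001,
         alpha = 0.05, coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
         pp4_min = 0.8, p_gw = 5e-8, palindrome_maf = 0.3,
         theta = cfg$theta),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

readFixtureSumStats <- function(dir, stem, trait, traitType) {
  readSumStats(file.path(dir, paste0(stem, ".tsv")), trait = trait,
               traitType = traitType)
}

#' Run the drug-target MR pipeline over a fixture directory
#'
#' Executes the requested stages in dependency order:
#' \code{select} (harmonization + genome-wide and cis instruments),
#' \code{mr} (pruning + model-selected univariable estimates, discovery and
#' replication), \code{mvmr} (joint lipid model per gene), \code{coloc},
#' \code{tissue}, \code{prioritize} (orientation, concordance, quartiles,
#' KS check, annotation matching) and \code{phewas}. Each stage writes a TSV
#' plus a JSON manifest carrying the config and seed into \code{outDir};
#' identical configs yield byte-identical TSVs. Requesting a stage whose
#' upstream stage is not part of the same call raises a dependency error
#' naming the missing stage.
#'
#' @param dir fixture/input directory (see \code{\link{makeFixtures}})
#' @param outDir output directory
#' @param stages character subset of
#'   c("select","mr","mvmr","coloc","tissue","prioritize","phewas")
#' @return invisibly, a list with the in-memory stage results
#' @export
runPipeline <- function(dir, outDir = file.path(dir, "out"),
                        stages = c("select", "mr", "mvmr", "coloc", "tissue",
                                   "prioritize", "phewas")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  manifest <- c(cfg, list(input_dir = dir))
  lipids <- names(LIPID_SLUGS)
  state <- new.env(parent = emptyenv())
  need <- function(what, stage) {
    if (!exists(what, envir = state))
      pkgError("dependency_error",
               sprintf("stage '%s' requires '%s' to have run", stage, what))
    get(what, envir = state)
  }
  ld <- readLDMatrix(file.path(dir, "ld.tsv"))
  genes <- readGeneAnnotation(file.path(dir, "genes.tsv"))

  if ("select" %in% stages) {
    outcomeD <- readFixtureSumStats(dir, "outcome_discovery", "outcome",
                                    "binary")
    outcomeR <- readFixtureSumStats(dir, "outcome_replication", "outcome",
                                    "binary")
    harmD <- harmR <- list()
    for (lip in lipids) {
      slug <- LIPID_SLUGS[lip]
      expD <- readFixtureSumStats(dir, paste0("exposure_discovery_", slug),
                                  lip, "quantitative")
      expR <- readFixtureSumStats(dir, paste0("exposure_replication_", slug),
                                  lip, "quantitative")
      harmD[[lip]] <- harmonize(expD, outcomeD,
                                palindromeMAF = cfg$palindrome_maf)
      harmR[[lip]] <- harmonize(expR, outcomeR,
                                palindromeMAF = cfg$palindrome_maf)
    }
    assign("harmD", harmD, envir = state)
    assign("harmR", harmR, envir = state)
    selected <- do.call(rbind, lapply(lipids, function(lip) {
      h <- harmD[[lip]]
      h[h$px <= cfg$p_max_genomewide &
          pmin(h$eaf, 1 - h$eaf) > cfg$maf_min, c("variant", "chrom", "pos")]
    }))
    selected <- selected[!duplicated(selected$variant), , drop = FALSE]
    gmap <- mapDruggableGenes(selected, genes, flank = cfg$flank_bp)
    assign("gmap", gmap, envir = state)
    writeStage(gmap, file.path(outDir, "selected_genes.tsv"), manifest)
  }

  if ("mr" %in% stages) {
    harmD <- need("harmD", "mr")
    harmR <- need("harmR", "mr")
    gmap <- need("gmap", "mr")
    gsyms <- unique(gmap$symbol)
    runMr <- function(harm, which) {
      rows <- list()
      instrs <- new.env(parent = emptyenv())
      for (lip in lipids) {
        ## genome-wide biomarker MR
        gw <- tryCatch({
          instr <- selectGenomewide(harm[[lip]], ld,
                                    pMax = cfg$p_max_genomewide,
                                    mafMin = cfg$maf_min,
                                    r2Max = cfg$r2_max,
                                    exposureTrait = lip)
          if (nrow(instr@pairs) >= 2)
            instr <- pruneOutliers(instr, qAlpha = cfg$q_alpha)
          selectModel(instr, alphaQ = cfg$alpha)
        }, error = function(e) NULL)
        if (!is.null(gw))
          rows[[length(rows) + 1]] <- cbind(lipid = lip, estimate(gw))
        for (sym in gsyms) {
          g <- genes[S4Vectors::mcols(genes)$symbol == sym]
          fit <- tryCatch({
            instr <- selectCis(harm[[lip]], g, ld, pMax = cfg$p_max_cis,
                               mafMin = cfg$maf_min, r2Max = cfg$r2_max,
                               flank = cfg$flank_bp, exposureTrait = lip)
            if (nrow(instr@pairs) >= 2)
              instr <- pruneOutliers(instr, qAlpha = cfg$q_alpha)
            assign(paste(sym, lip, sep = "|"), instr, envir = instrs)
            selectModel(instr, alphaQ = cfg$alpha)
          }, error = function(e) NULL)
          if (!is.null(fit))
            rows[[length(rows) + 1]] <- cbind(lipid = lip, estimate(fit))
        }
      }
      list(table = do.call(rbind, rows), instrs = as.list(instrs))
    }
    mrD <- runMr(harmD, "discovery")
    mrR <- runMr(harmR, "replication")
    assign("mrD", mrD, envir = state)
    assign("mrR", mrR, envir = state)
    writeStage(mrD$table, file.path(outDir, "mr_discovery.tsv"), manifest)
    writeStage(mrR$table, file.path(outDir, "mr_replication.tsv"), manifest)
  }

  if ("mvmr" %in% stages) {
    harmD <- need("harmD", "mvmr")
    gmap <- need("gmap", "mvmr")
    rows <- list()
    for (sym in unique(gmap$symbol)) {
      g <- genes[S4Vectors::mcols(genes)$symbol == sym]
      fit <- tryCatch(mvmrCis(harmD, g, ld, pMax = cfg$p_max_cis,
                              mafMin = cfg$maf_min, r2Max = cfg$r2_max,
                              flank = cfg$flank_bp, unit = sym),
                      error = function(e) NULL)
      if (!is.null(fit)) rows[[length(rows) + 1]] <- estimate(fit)
    }
    mvmrTab <- do.call(rbind, rows)
    assign("mvmrTab", mvmrTab, envir = state)
    if (!is.null(mvmrTab))
      writeStage(mvmrTab, file.path(outDir, "mvmr.tsv"), manifest)
  }

  if ("coloc" %in% stages) {
    harmD <- need("harmD", "coloc")
    gmap <- need("gmap", "coloc")
    rows <- list()
    for (sym in unique(gmap$symbol)) {
      g <- genes[S4Vectors::mcols(genes)$symbol == sym]
      lo <- GenomicRanges::start(g) - cfg$flank_bp
      hi <- GenomicRanges::end(g) + cfg$flank_bp
      for (lip in lipids) {
        h <- harmD[[lip]]
        inwin <- h$chrom == as.character(GenomicRanges::seqnames(g)) &
          h$pos >= lo & h$pos <= hi
        if (!any(inwin)) next
        hr <- h[inwin, , drop = FALSE]
        ex <- data.frame(variant = hr$variant, beta = hr$bx, se = hr$sx,
                         pvalue = hr$px, eaf = hr$eaf)
        oy <- data.frame(variant = hr$variant, beta = hr$by, se = hr$sy,
                         pvalue = hr$py, eaf = hr$eaf)
        res <- tryCatch(
          colocalizeRegion(ex, oy, ld,
                           priors = colocPriors(cfg$coloc_p1, cfg$coloc_p2,
                                                cfg$coloc_p12),
                           pp4Min = cfg$pp4_min, mafMin = cfg$maf_min),
          error = function(e) NULL)
        if (is.null(res)) next
        for (si in seq_along(res)) {
          r <- res[[si]]
          rows[[length(rows) + 1]] <- data.frame(
            gene = sym, lipid = lip, signal = si, lead = r@lead,
            t(setNames(as.numeric(r@pp), paste0("PP", 0:4))),
            n_variants = as.integer(r@nVariants), colocalized = r@decision,
            stringsAsFactors = FALSE)
        }
      }
    }
    colocTab <- do.call(rbind, rows)
    assign("colocTab", colocTab, envir = state)
    if (!is.null(colocTab))
      writeStage(colocTab, file.path(outDir, "coloc.tsv"), manifest)
  }

  if ("tissue" %in% stages) {
    expr <- readExpressionMatrix(file.path(dir, "expression.tsv"))
    tisTab <- tissueSpecificity(expr)
    assign("tisTab", tisTab, envir = state)
    writeStage(tisTab, file.path(outDir, "tissue.tsv"), manifest)
  }

  if ("prioritize" %in% stages) {
    mrD <- need("mrD", "prioritize")
    mrR <- need("mrR", "prioritize")
    orientTab <- function(tab) {
      cis <- tab[tab$unit != "genome-wide", , drop = FALSE]
      do.call(rbind, lapply(seq_len(nrow(cis)), function(i) {
        r <- cis[i, ]
        est <- new("MREstimate", beta = r$beta, se = r$se,
                   ciLow = log(r$ci_low), ciHigh = log(r$ci_high),
                   pvalue = r$pvalue, or = r$or, intercept = NA_real_,
                   interceptSE = NA_real_, q = r$q, qDf = r$q_df,
                   qPvalue = r$q_pvalue, nSnps = r$n_snps, family = r$family,
                   effects = r$effects, unit = r$unit)
        orientEstimate(est, r$lipid, alpha = cfg$alpha)
      }))
    }
    orD <- orientTab(mrD$table)
    orR <- orientTab(mrR$table)
    conc <- tryCatch(replicationConcordance(orD, orR, alpha = cfg$alpha),
                     error = function(e) NULL)
    quart <- summarizeQuartiles(orD)
    ksRes <- if (nrow(orD) >= 5) ksUniformity(orD$pvalue) else NULL
    annTab <- read.table(file.path(dir, "drug_annotations.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
    matches <- matchAnnotations(annTab)
    report <- orD
    names(report)[names(report) == "unit"] <- "gene"
    if (!is.null(conc)) {
      key <- paste(conc$per_unit$unit, conc$per_unit$lipid, sep = "|")
      idx <- match(paste(report$gene, report$lipid, sep = "|"), key)
      report$replication_or <- conc$per_unit$replication_or[idx]
      report$replication_p <- conc$per_unit$replication_p[idx]
      report$concordant <- conc$per_unit$concordant[idx]
    }
    if (exists("colocTab", envir = state) &&
        !is.null(get("colocTab", envir = state))) {
      ct <- get("colocTab", envir = state)
      best <- ct[order(ct$gene, ct$lipid, -ct$PP4), , drop = FALSE]
      best <- best[!duplicated(paste(best$gene, best$lipid)), , drop = FALSE]
      idx <- match(paste(report$gene, report$lipid, sep = "|"),
                   paste(best$gene, best$lipid, sep = "|"))
      report$pp4 <- best$PP4[idx]
      report$colocalized <- best$colocalized[idx]
    }
    if (exists("tisTab", envir = state)) {
      tt <- get("tisTab", envir = state)
      idx <- match(report$gene, tt$gene)
      report$tau <- tt$tau[idx]
      report$top_tissues <- tt$top_tissues[idx]
    }
    report$annotation_match <- report$gene %in% matches$gene
    assign("report", report, envir = state)
    assign("concordance", conc, envir = state)
    writeStage(report, file.path(outDir, "prioritization.tsv"), manifest)
    writeStage(quart, file.path(outDir, "or_quartiles.tsv"), manifest)
    if (!is.null(ksRes))
      jsonlite::write_json(ksRes, file.path(outDir, "ks_uniformity.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  if ("phewas" %in% stages) {
    phenoFiles <- list.files(dir, pattern = "^phenotype_.*\\.tsv$",
                             full.names = TRUE)
    phenos <- lapply(phenoFiles, function(f)
      readSumStats(f, trait = sub("^phenotype_(.*)\\.tsv$", "\\1",
                                  basename(f)),
                   traitType = "binary"))
    names(phenos) <- vapply(phenos, trait, "")
    phewasTab <- phewasScan(genes, phenos, flank = cfg$flank_bp,
                            pGw = cfg$p_gw,
                            palindromeMAF = cfg$palindrome_maf)
    assign("phewasTab", phewasTab, envir = state)
    writeStage(phewasTab, file.path(outDir, "phewas.tsv"), manifest)
  }
  invisible(as.list(state))
}

#' Multivariable cis MR for one gene from harmonized lipid tables
#'
#' Builds the union of per-lipid cis instruments in the gene window (p-value
#' filter on the minimum across lipids, then clumping), aligns the three
#' exposure effect columns, and fits \code{\link{mvmrFit}}.
#'
#' @param harmonized named list (by lipid) of harmonized pair tables sharing
#'   the outcome dataset
#' @param gene single-range \code{GRanges}
#' @param ld \linkS4class{LDMatrix}
#' @param pMax,mafMin,r2Max,flank selection parameters as in
#'   \code{\link{selectCis}}
#' @param unit label for the result
#' @return an \linkS4class{MVMREstimate}
#' @export
mvmrCis <- function(harmonized, gene, ld, pMax = 1e-4, mafMin = 0.01,
                    r2Max = 0.4, flank = 50000, unit = "gene") {
  lo <- GenomicRanges::start(gene) - flank
  hi <- GenomicRanges::end(gene) + flank
  chr <- as.character(GenomicRanges::seqnames(gene))
  shared <- Reduce(intersect, lapply(harmonized, function(h) h$variant))
  base <- harmonized[[1]]
  base <- base[match(shared, base$variant), , drop = FALSE]
  inwin <- base$chrom == chr & base$pos >= lo & base$pos <= hi
  base <- base[inwin, , drop = FALSE]
  if (nrow(base) == 0)
    pkgError("empty_instrument_error", "no variants in gene window")
  pmin_all <- Reduce(pmin, lapply(harmonized, function(h)
    h$px[match(base$variant, h$variant)]))
  maf <- pmin(base$eaf, 1 - base$eaf)
  keep <- pmin_all <= pMax & maf > mafMin
  cand <- base[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    pkgError("empty_instrument_error", "no instruments pass cis threshold")
  kept <- ldClump(data.frame(variant = cand$variant,
                             pvalue = pmin_all[keep], chrom = cand$chrom,
                             pos = cand$pos), ld, r2Max)
  X <- vapply(harmonized, function(h) h$bx[match(kept, h$variant)],
              numeric(length(kept)))
  if (length(kept) == 1) X <- matrix(X, nrow = 1,
                                     dimnames = list(NULL, names(harmonized)))
  by <- base$by[match(kept, base$variant)]
  sy <- base$sy[match(kept, base$variant)]
  mvmrFit(X, by, sy, LDMatrix(ld@r[kept, kept, drop = FALSE], kept),
          unit = unit)
}
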