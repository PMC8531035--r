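## Synthetic two-sample GWAS generator with known causal architecture.
##
## Emulates the statistical structure of the real inputs: AR(1)-correlated
## variants, up to three correlated quantitative lipid exposures, a binary
## outcome on the log-odds scale, non-overlapping exposure and outcome
## cohorts, and a discovery/replication pair of unequal size. Defaults mirror
## the study conditions: a 5000-individual LD reference, discovery exposure
## n = 188577 with outcome n = 184305 (case fraction 0.33), replication
## exposure n = 33029 with outcome n = 296525 (case fraction 0.1165).

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic generators. The
#' per-exposure causal effects (standardized-genotype scale) are drawn once,
#' deterministically from \code{seed}, so a config fully determines the true
#' architecture.
#'
#' @param nVariants number of variants
#' @param nRef LD reference panel size (default 5000)
#' @param rho AR(1) LD decay parameter in [0,1)
#' @param mafRange range the per-variant MAFs are drawn from, within (0, 0.5]
#' @param nExposure,nOutcome GWAS sample sizes (two-sample: disjoint cohorts)
#' @param theta true causal effect(s) of the exposure(s) on the outcome,
#'   log-odds per SD; its length sets the number of exposures
#' @param nCausal causal variants per exposure
#' @param h2 variance in each exposure explained by its causal variants
#' @param pleiotropy per-variant direct (standardized) outcome effects,
#'   length nVariants; default none
#' @param blockSize optional number of variants per independent LD block;
#'   NULL (default) keeps one AR(1) chain over all variants
#' @param caseFraction outcome prevalence in (0,1)
#' @param exposureCor residual correlation matrix between exposures
#' @param seed integer seed; mandatory
#' @return a validated list of class "SimConfig" with an added
#'   \code{causalEffects} (nVariants x nExposures) matrix
#' @export
simConfig <- function(nVariants = 60, nRef = 5000, rho = 0.8,
                      mafRange = c(0.05, 0.5), nExposure = 188577,
                      nOutcome = 184305, theta = 0.4, nCausal = 20,
                      h2 = 0.1, pleiotropy = NULL, caseFraction = 0.33,
                      exposureCor = NULL, blockSize = NULL, seed = 1) {
  stopifnot(rho >= 0, rho < 1, mafRange[1] > 0, mafRange[2] <= 0.5,
            caseFraction > 0, caseFraction < 1, nCausal <= nVariants,
            length(theta) >= 1)
  k <- length(theta)
  if (is.null(exposureCor)) {
    exposureCor <- diag(k)
    if (k == 3) {
      ## realistic lipid phenotype correlations (LDL, HDL, TG order)
      exposureCor[1, 2] <- exposureCor[2, 1] <- -0.1
      exposureCor[1, 3] <- exposureCor[3, 1] <- 0.3
      exposureCor[2, 3] <- exposureCor[3, 2] <- -0.4
    }
  }
  set.seed(childSeed(seed, 1))
  B <- matrix(0, nVariants, k)
  for (j in seq_len(k)) {
    idx <- sort(sample.int(nVariants, nCausal))
    B[idx, j] <- rnorm(nCausal, 0, sqrt(h2 / nCausal))
  }
  cfg <- list(nVariants = nVariants, nRef = nRef, rho = rho,
              mafRange = mafRange, nExposure = nExposure,
              nOutcome = nOutcome, theta = theta, nCausal = nCausal,
              h2 = h2,
              pleiotropy = pleiotropy %||% rep(0, nVariants),
              caseFraction = caseFraction, exposureCor = exposureCor,
              blockSize = blockSize,
              causalEffects = B, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

## AR(1) latent Gaussian matrix: n x m with corr(i,j) = rho^|i-j| across
## columns; the chain restarts at each block start, making blocks independent
latentAR1 <- function(n, m, rho, blockSize = NULL) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    starts <- if (is.null(blockSize)) 1L else
      seq(1L, m, by = as.integer(blockSize))
    for (j in 2:m) {
      if (!(j %in% starts)) z[, j] <- rho * z[, j - 1] + s * z[, j]
    }
  }
  z
}

## dosages for a cohort: two dichotomized AR(1) haplotypes per individual
drawDosages <- function(n, maf, rho, blockSize = NULL) {
  m <- length(maf)
  thr <- qnorm(maf)
  h1 <- sweep(latentAR1(n, m, rho, blockSize), 2, thr, "<") * 1
  h2 <- sweep(latentAR1(n, m, rho, blockSize), 2, thr, "<") * 1
  h1 + h2
}

simVariantTable <- function(nVariants, blockSize = NULL) {
  ## non-palindromic allele pairs so harmonization keeps everything
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  idx <- ((seq_len(nVariants) - 1) %% 4) + 1
  pos <- 1000000L + (seq_len(nVariants) - 1L) * 5000L
  if (!is.null(blockSize)) {
    ## 200 kb gaps between independent blocks so +/-50 kb gene windows
    ## never span two blocks
    block <- (seq_len(nVariants) - 1L) %/% as.integer(blockSize)
    pos <- pos + block * 200000L
  }
  data.frame(chrom = "1", pos = pos,
             effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
             stringsAsFactors = FALSE)
}

#' Simulate an LD reference panel
#'
#' Latent multivariate normal haplotypes with corr(i,j) = rho^|i-j|,
#' dichotomized per variant at the quantile implied by its sampled MAF and
#' summed over two haplotypes to dosages. The returned LD matrix is the
#' empirical dosage correlation.
#'
#' @param cfg a \code{\link{simConfig}}
#' @return list with panel (\linkS4class{ReferencePanel}), ld
#'   (\linkS4class{LDMatrix}) and maf (the target MAFs)
#' @export
simulatePanel <- function(cfg) {
  set.seed(childSeed(cfg$seed, 2))
  maf <- runif(cfg$nVariants, cfg$mafRange[1], cfg$mafRange[2])
  vt <- simVariantTable(cfg$nVariants, cfg$blockSize)
  dos <- drawDosages(cfg$nRef, maf, cfg$rho, cfg$blockSize)
  panel <- ReferencePanel(dos, vt, maf = pmin(colMeans(dos) / 2,
                                              1 - colMeans(dos) / 2))
  list(panel = panel, ld = computeLD(panel), maf = maf)
}

## per-config derived quantities shared by both GWAS modes
simTruth <- function(cfg, ld, maf) {
  B <- cfg$causalEffects
  R <- ld@r
  margX <- R %*% B                        # standardized marginal exposure effects
  liab <- drop(B %*% cfg$theta) + cfg$pleiotropy
  margY <- drop(R %*% liab)               # standardized marginal liability effects
  sdg <- sqrt(2 * maf * (1 - maf))
  list(B = B, margX = margX, margY = margY, sdg = sdg)
}

sumstatsFromStd <- function(vt, bStd, seStd, sdg, eaf, n, trait, traitType) {
  beta <- bStd / sdg
  se <- seStd / sdg
  rec <- cbind(vt, data.frame(beta = beta, se = se,
                              pvalue = pmax(zPvalue(beta, se), 1e-300),
                              eaf = eaf, n = n))
  SumStats(rec, trait = trait, traitType = traitType)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates per-variant marginal association statistics for the configured
#' exposures (quantitative, per-SD scale) and the binary outcome (log-odds
#' scale) on two disjoint cohorts.
#'
#' Two modes produce draws from the same data-generating process:
#' \code{"individual"} simulates cohort-level genotypes and phenotypes and
#' runs per-variant regressions (linear for exposures; logistic for the
#' outcome, either a one-step score estimator or full \code{glm}), while
#' \code{"summary"} samples the marginal estimate vector directly from its
#' asymptotic multivariate normal distribution given the LD structure, which
#' makes large repetition grids cheap.
#'
#' @param sim a panel list from \code{\link{simulatePanel}}
#' @param cfg the \code{\link{simConfig}} used to build the panel
#' @param mode "summary" (asymptotic sampling) or "individual" (cohort-level)
#' @param binaryMethod outcome regression for individual mode: "score"
#'   (one-step from the null) or "glm" (full logistic fits)
#' @param seed integer seed for the cohort draw
#' @return list with exposures (list of \linkS4class{SumStats}) and outcome
#'   (a \linkS4class{SumStats})
#' @export
simulateGwas <- function(sim, cfg, mode = c("summary", "individual"),
                         binaryMethod = c("score", "glm"), seed = cfg$seed) {
  mode <- match.arg(mode)
  binaryMethod <- match.arg(binaryMethod)
  k <- length(cfg$theta)
  traits <- if (k == 3) c("LDL-C", "HDL-C", "TG") else
    paste0("exposure", seq_len(k))
  truth <- simTruth(cfg, sim$ld, sim$maf)
  vt <- sim$panel@variants
  eaf <- sim$maf                       # alleles coded so EAF = MAF here
  if (mode == "summary") {
    set.seed(childSeed(seed, 3))
    R <- sim$ld@r
    m <- cfg$nVariants
    ## exposures: vec(bhat) ~ MVN(vec(margX), (exposureCor x R)/n)
    covX <- kronecker(cfg$exposureCor, R) / cfg$nExposure
    covX <- covX + diag(1e-10, nrow(covX))
    bx <- matrix(drop(c(truth$margX) + crossprod(chol(covX), rnorm(m * k))),
                 m, k)
    exposures <- lapply(seq_len(k), function(j)
      sumstatsFromStd(vt, bx[, j], rep(1 / sqrt(cfg$nExposure), m),
                      truth$sdg, eaf, cfg$nExposure, traits[j],
                      "quantitative"))
    phi <- cfg$caseFraction * (1 - cfg$caseFraction)
    covY <- R / (cfg$nOutcome * phi) + diag(1e-10, m)
    by <- drop(truth$margY + crossprod(chol(covY), rnorm(m)))
    outcome <- sumstatsFromStd(vt, by, rep(1 / sqrt(cfg$nOutcome * phi), m),
                               truth$sdg, eaf, cfg$nOutcome, "outcome",
                               "binary")
    return(list(exposures = exposures, outcome = outcome))
  }
  ## individual mode
  set.seed(childSeed(seed, 4))
  m <- cfg$nVariants
  ## exposure cohort
  G <- drawDosages(cfg$nExposure, sim$maf, cfg$rho, cfg$blockSize)
  Gs <- scale(G)
  expl <- diag(t(truth$B) %*% sim$ld@r %*% truth$B)
  noiseSd <- sqrt(pmax(1 - expl, 0.05))
  E <- Gs %*% truth$B +
    matrix(rnorm(cfg$nExposure * k), cfg$nExposure, k) %*%
    chol(cfg$exposureCor) * rep(noiseSd, each = cfg$nExposure)
  exposures <- vector("list", k)
  for (j in seq_len(k)) {
    y <- drop(E[, j])
    gv <- apply(G, 2, var)
    bj <- drop(cov(y, G)) / gv
    resvar <- pmax(var(y) - bj^2 * gv, 1e-12)
    sj <- sqrt(resvar / (gv * (cfg$nExposure - 2)))
    rec <- cbind(vt, data.frame(beta = bj, se = sj,
                                pvalue = pmax(zPvalue(bj, sj), 1e-300),
                                eaf = colMeans(G) / 2, n = cfg$nExposure))
    exposures[[j]] <- SumStats(rec, traits[j], "quantitative")
  }
  ## outcome cohort (independent)
  G2 <- drawDosages(cfg$nOutcome, sim$maf, cfg$rho, cfg$blockSize)
  G2s <- scale(G2)
  E2 <- G2s %*% truth$B +
    matrix(rnorm(cfg$nOutcome * k), cfg$nOutcome, k) %*%
    chol(cfg$exposureCor) * rep(noiseSd, each = cfg$nOutcome)
  eta <- qlogis(cfg$caseFraction) + drop(E2 %*% cfg$theta) +
    drop(G2s %*% cfg$pleiotropy)
  yb <- rbinom(cfg$nOutcome, 1, plogis(eta))
  ybar <- mean(yb)
  if (binaryMethod == "score") {
    g2c <- sweep(G2, 2, colMeans(G2))
    ss <- colSums(g2c^2)
    by <- drop(crossprod(g2c, yb - ybar)) / (ybar * (1 - ybar) * ss)
    sy <- 1 / sqrt(ybar * (1 - ybar) * ss)
  } else {
    by <- sy <- numeric(m)
    for (j in seq_len(m)) {
      f <- summary(glm(yb ~ G2[, j], family = binomial()))$coefficients
      by[j] <- f[2, 1]
      sy[j] <- f[2, 2]
    }
  }
  rec <- cbind(vt, data.frame(beta = by, se = sy,
                              pvalue = pmax(zPvalue(by, sy), 1e-300),
                              eaf = colMeans(G2) / 2, n = cfg$nOutcome))
  outcome <- SumStats(rec, "outcome", "binary")
  list(exposures = exposures, outcome = outcome)
}

#' Simulate a discovery/replication dataset pair
#'
#' Two independent (exposure, outcome) dataset pairs sharing the same true
#' causal architecture but with independent noise and distinct (typically
#' smaller replication) sample sizes, emulating the two-cohort design.
#'
#' @param cfg a \code{\link{simConfig}} (discovery sizes)
#' @param nReplicationExposure replication exposure sample size
#'   (default 33029)
#' @param nReplicationOutcome replication outcome sample size
#'   (default 296525)
#' @param replicationCaseFraction replication outcome prevalence
#' @param mode passed to \code{\link{simulateGwas}}
#' @return list with sim (the shared panel), discovery and replication, each
#'   a list(exposures, outcome)
#' @export
simulateReplicationPair <- function(cfg, nReplicationExposure = 33029,
                                    nReplicationOutcome = 296525,
                                    replicationCaseFraction = 0.1165,
                                    mode = "summary") {
  sim <- simulatePanel(cfg)
  discovery <- simulateGwas(sim, cfg, mode = mode,
                            seed = childSeed(cfg$seed, 10))
  repCfg <- cfg
  repCfg$nExposure <- nReplicationExposure
  repCfg$nOutcome <- nReplicationOutcome
  repCfg$caseFraction <- replicationCaseFraction
  replication <- simulateGwas(sim, repCfg, mode = mode,
                              seed = childSeed(cfg$seed, 11))
  list(sim = sim, discovery = discovery, replication = replication)
}

#' Simulate a gene x tissue normalized-expression matrix
#'
#' Pattern "one-hot" concentrates all expression in one tissue (tau = 1),
#' "uniform" spreads it identically (tau = 0), and "graded" draws log-normal
#' values with one planted dominant tissue.
#'
#' @param nGenes number of genes
#' @param tissues tissue labels (>= 2)
#' @param patterns per-gene pattern, recycled over genes
#' @param dominantFold fold-elevation of the dominant tissue for "graded"
#' @param seed integer seed
#' @return numeric matrix genes x tissues with informative dimnames
#' @export
simulateExpression <- function(nGenes, tissues,
                               patterns = c("one-hot", "uniform", "graded"),
                               dominantFold = 10, seed = 1) {
  stopifnot(length(tissues) >= 2)
  set.seed(childSeed(seed, 5))
  patterns <- rep(patterns, length.out = nGenes)
  m <- matrix(0, nGenes, length(tissues),
              dimnames = list(paste0("GENE", seq_len(nGenes)), tissues))
  for (i in seq_len(nGenes)) {
    m[i, ] <- switch(patterns[i],
      "one-hot" = { v <- rep(0, length(tissues))
                    v[sample.int(length(tissues), 1)] <- 50; v },
      "uniform" = rep(10, length(tissues)),
      "graded" = { v <- exp(rnorm(length(tissues), log(5), 0.3))
                   v[sample.int(length(tissues), 1)] <- dominantFold * max(v)
                   v },
      stop("unknown pattern: ", patterns[i]))
  }
  attr(m, "patterns") <- patterns
  m
}
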