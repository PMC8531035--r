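## Bayesian colocalization of exposure and outcome association signals via
## Wakefield approximate Bayes factors, preceded by a stepwise (COJO-style)
## conditional decomposition of the exposure region.

#' Colocalization priors
#'
#' Per-variant prior probabilities of association with the exposure only
#' (p1), the outcome only (p2), or both (p12). Defaults are the standard
#' coloc priors.
#'
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5)
#' @return named list; validated
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1)
  list(p1 = p1, p2 = p2, p12 = p12)
}

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's ABF under a normal effect prior with SD \code{priorSD}: with
#' V = se^2, r = W^2/(W^2+V) and z = beta/se,
#' labf = (log(1-r) + r z^2)/2.
#'
#' @param beta,se association estimate and standard error (se > 0)
#' @param priorSD prior effect SD W (0.15 for per-SD quantitative traits,
#'   0.2 on the log-odds scale for binary traits)
#' @return log approximate Bayes factor (vectorized)
#' @export
labf <- function(beta, se, priorSD = 0.15) {
  stopifnot(all(se > 0), priorSD > 0)
  V <- se^2
  r <- priorSD^2 / (priorSD^2 + V)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

#' Colocalization posterior probabilities from per-variant log ABFs
#'
#' Standard single-causal-variant hypothesis sums computed in log space
#' (log-sum-exp): H0 no association; H1 exposure only; H2 outcome only;
#' H3 two distinct causal variants; H4 one shared causal variant.
#'
#' @param labfX,labfY per-variant log ABFs for the two traits, aligned on the
#'   same variant list
#' @param priors list from \code{\link{colocPriors}}
#' @param pp4Min decision threshold; colocalized iff PP4 strictly exceeds it
#' @param lead lead-variant label carried through to the result
#' @return a \linkS4class{ColocResult}
#' @export
colocPP <- function(labfX, labfY, priors = colocPriors(), pp4Min = 0.8,
                    lead = "") {
  if (length(labfX) != length(labfY))
    pkgError("alignment_error", "labf vectors must align on the same variants")
  p <- length(labfX)
  if (p < 1) pkgError("alignment_error", "empty region")
  lsx <- logSumExp(labfX)
  lsy <- logSumExp(labfY)
  lsxy <- logSumExp(labfX + labfY)
  lH0 <- 0
  lH1 <- log(priors$p1) + lsx
  lH2 <- log(priors$p2) + lsy
  ## H3: sum over ordered pairs i != j = (sum_i)(sum_j) - sum_i (x_i y_i)
  lH3 <- if (p >= 2) {
    d <- lsxy - (lsx + lsy)
    ## guard: numerically d can creep to >= 0 when one variant dominates both
    log(priors$p1) + log(priors$p2) + lsx + lsy +
      (if (d < 0) log1p(-exp(d)) else -Inf)
  } else -Inf
  lH4 <- log(priors$p12) + lsxy
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logSumExp(lh))
  pp <- pp / sum(pp)
  new("ColocResult", pp = setNames(pp, paste0("PP", 0:4)), nVariants = p,
      priors = priors, decision = isTRUE(pp[5] > pp4Min), lead = lead)
}

#' Stepwise conditional decomposition of a region
#'
#' COJO-style forward selection on summary statistics: iteratively selects the
#' variant with the smallest conditional p-value below \code{pEntry}, skipping
#' candidates whose r-squared with any selected lead exceeds
#' \code{r2Collinear}; conditional effects are computed by joint GLS of the
#' selected set plus the candidate, using the reference LD. Stops when no
#' candidate passes.
#'
#' @param region data.frame with columns variant, beta, se, pvalue
#' @param ld \linkS4class{LDMatrix} aligned to the region variants
#' @param pEntry entry threshold (default 5e-8)
#' @param r2Collinear collinearity guard (default 0.9)
#' @return list of signals; each has lead, and per-variant conditional
#'   beta/se/p for the whole region conditioning on the other leads
#' @export
stepwiseConditional <- function(region, ld, pEntry = 5e-8,
                                r2Collinear = 0.9) {
  stopifnot(nrow(region) >= 1)
  ids <- region$variant
  R <- ld@r[ids, ids, drop = FALSE]
  leads <- character(0)
  repeat {
    cond <- conditionalStats(region, R, leads, r2Collinear)
    ok <- which(is.finite(cond$pvalue) & cond$pvalue < pEntry &
                  !(ids %in% leads) & !cond$collinear)
    if (length(ok) == 0) break
    leads <- c(leads, ids[ok[which.min(cond$pvalue[ok])]])
  }
  lapply(leads, function(lv) {
    others <- setdiff(leads, lv)
    cs <- conditionalStats(region, R, others, r2Collinear)
    list(lead = lv,
         stats = data.frame(variant = ids, conditional_beta = cs$beta,
                            conditional_se = cs$se,
                            conditional_p = cs$pvalue,
                            stringsAsFactors = FALSE))
  })
}

## conditional marginal stats of every region variant given a lead set.
## With no leads this returns the marginal statistics unchanged.
conditionalStats <- function(region, R, leads, r2Collinear = 0.9) {
  ids <- region$variant
  b <- region$beta
  se <- region$se
  n <- length(ids)
  if (length(leads) == 0)
    return(list(beta = b, se = se, pvalue = region$pvalue,
                collinear = rep(FALSE, n)))
  li <- match(leads, ids)
  Rll <- R[li, li, drop = FALSE]
  collinear <- rep(FALSE, n)
  beta_c <- b
  se_c <- se
  ## standardized scale: z_j = b_j/se_j; conditional z via LD projection
  w <- 1 / se
  bs <- b * w
  sol <- ldSolve(Rll, 1e-8, ridgeMax = 1e-6)
  Rll_r <- Rll
  diag(Rll_r) <- diag(Rll_r) + sol$eps
  Rll_inv <- chol2inv(chol(Rll_r))
  bl <- bs[li]
  for (j in seq_len(n)) {
    if (j %in% li) {
      beta_c[j] <- NA_real_
      se_c[j] <- NA_real_
      next
    }
    rj <- R[j, li]
    shrink <- drop(rj %*% Rll_inv %*% rj)
    if (shrink > r2Collinear) {
      collinear[j] <- TRUE
      beta_c[j] <- NA_real_
      se_c[j] <- NA_real_
      next
    }
    bs_c <- bs[j] - drop(rj %*% Rll_inv %*% bl)
    var_c <- max(1 - shrink, 1e-12)
    beta_c[j] <- bs_c / w[j]
    se_c[j] <- sqrt(var_c) / w[j]
  }
  pv <- ifelse(is.na(beta_c), NA_real_, zPvalue(beta_c, se_c))
  list(beta = beta_c, se = se_c, pvalue = pv, collinear = collinear)
}

#' Colocalize exposure and outcome signals in one region
#'
#' Applies the MAF filter, aligns the two traits on shared variants, runs the
#' stepwise conditional decomposition on the exposure region, and computes
#' colocalization posteriors per exposure signal: marginal statistics when at
#' most one signal is found, conditional statistics (conditioning each signal
#' on the other leads, for both traits) otherwise. The decision requires PP4
#' strictly above \code{pp4Min}.
#'
#' @param exposureRegion,outcomeRegion data.frames with columns variant, beta,
#'   se, pvalue, eaf
#' @param ld \linkS4class{LDMatrix} covering the shared variants
#' @param priors list from \code{\link{colocPriors}}
#' @param pp4Min decision threshold (default 0.8, strict)
#' @param mafMin MAF inclusion filter (default 0.01, strict)
#' @param priorSDX,priorSDY ABF prior effect SDs for the two traits
#' @param pEntry entry threshold for the conditional decomposition
#' @return list of \linkS4class{ColocResult}, one per exposure signal (one
#'   marginal result when no signal passes the entry threshold)
#' @export
colocalizeRegion <- function(exposureRegion, outcomeRegion, ld,
                             priors = colocPriors(), pp4Min = 0.8,
                             mafMin = 0.01, priorSDX = 0.15, priorSDY = 0.2,
                             pEntry = 5e-8) {
  keepx <- pmin(exposureRegion$eaf, 1 - exposureRegion$eaf) > mafMin
  keepy <- pmin(outcomeRegion$eaf, 1 - outcomeRegion$eaf) > mafMin
  ex <- exposureRegion[keepx, , drop = FALSE]
  oy <- outcomeRegion[keepy, , drop = FALSE]
  shared <- intersect(ex$variant, oy$variant)
  if (length(shared) == 0)
    pkgError("alignment_error", "regions share no variants after MAF filter")
  ex <- ex[match(shared, ex$variant), , drop = FALSE]
  oy <- oy[match(shared, oy$variant), , drop = FALSE]
  sub <- LDMatrix(ld@r[shared, shared, drop = FALSE], shared)
  signals <- stepwiseConditional(ex, sub, pEntry = pEntry)
  if (length(signals) <= 1) {
    lead <- if (length(signals) == 1) signals[[1]]$lead else ""
    res <- colocPP(labf(ex$beta, ex$se, priorSDX),
                   labf(oy$beta, oy$se, priorSDY),
                   priors, pp4Min, lead = lead)
    return(list(res))
  }
  R <- sub@r
  lapply(signals, function(sig) {
    others <- setdiff(vapply(signals, `[[`, "", "lead"), sig$lead)
    keep <- !(shared %in% others)
    cx <- sig$stats[keep, , drop = FALSE]
    cy <- conditionalStats(oy, R, others)
    lx <- labf(cx$conditional_beta, cx$conditional_se, priorSDX)
    ly <- labf(cy$beta[keep], cy$se[keep], priorSDY)
    ok <- is.finite(lx) & is.finite(ly)
    colocPP(lx[ok], ly[ok], priors, pp4Min, lead = sig$lead)
  })
}
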