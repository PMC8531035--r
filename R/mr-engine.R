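## LD-aware MR estimation.
##
## Model: by = theta * bx (+ intercept for Egger) with error covariance
## Sigma = diag(sy) %*% R %*% diag(sy), R the signed LD matrix. First-order
## covariance only: uncertainty in bx is ignored (standard two-sample
## practice); the resulting weak-instrument attenuation is documented, not
## corrected.

## invert Sigma via Cholesky; the ridge is applied lazily (exact first, then
## ridgeEps escalating tenfold) so well-conditioned LD is left untouched
ldSolve <- function(R, ridgeEps = 1e-8, ridgeMax = 1e-4) {
  eps <- 0
  repeat {
    Rr <- R
    diag(Rr) <- diag(Rr) + eps
    ch <- tryCatch(chol(Rr), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, eps = eps))
    if (eps >= ridgeMax)
      pkgError("conditioning_error",
               sprintf("LD matrix singular even at ridge %.1e", eps))
    eps <- if (eps == 0) ridgeEps else eps * 10
  }
}

#' Wald ratio estimate from a single instrument
#'
#' ratio = by/bx with first-order delta-method standard error
#' sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4).
#'
#' @param bx,sx exposure effect and SE
#' @param by,sy outcome effect and SE
#' @return list with ratio and se
#' @export
waldRatio <- function(bx, sx, by, sy) {
  if (bx == 0) pkgError("degenerate_instrument_error", "bx must be nonzero")
  list(ratio = by / bx, se = sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4))
}

## core GLS machinery shared by glsFit and mvmrFit.
## X: design matrix; by, sy: outcome effects/SEs; R: LD.
glsCore <- function(X, by, sy, R, ridgeEps = 1e-8) {
  n <- length(by)
  k <- ncol(X)
  sol <- ldSolve(R, ridgeEps)
  ## whiten: Sigma = D R D => L = chol(R); solve through D and L
  Lt <- sol$chol                       # upper triangular, R = t(Lt) %*% Lt
  Xs <- X / sy                         # D^-1 X
  ys <- by / sy
  Xw <- backsolve(Lt, Xs, transpose = TRUE)   # L^-T applied: whitened design
  yw <- backsolve(Lt, ys, transpose = TRUE)
  XtX <- crossprod(Xw)
  cn <- kappa(XtX, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10)
    pkgError("collinearity_error",
             sprintf("rank-deficient design (condition number %.3g)", cn))
  XtXinv <- solve(XtX)
  bhat <- drop(XtXinv %*% crossprod(Xw, yw))
  resid_w <- yw - Xw %*% bhat
  q <- drop(crossprod(resid_w))
  df <- n - k
  ## hat-matrix leverages in the whitened space
  H <- Xw %*% XtXinv %*% t(Xw)
  list(coef = bhat, vcov = XtXinv, q = q, df = df,
       qPvalue = if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_,
       leverage = diag(H), contributions = drop(resid_w)^2,
       ridge = sol$eps)
}

#' Generalized least squares IVW / MR-Egger fit
#'
#' Regression of the outcome effects on the exposure effects under error
#' covariance Sigma = diag(sy) R diag(sy): through the origin for IVW, with a
#' free intercept for Egger. Before an Egger fit the instruments are oriented
#' so every bx >= 0 (by sign-flipped accordingly). Random effects inflates all
#' variances by max(1, Q/df) with df = n_snps - parameters.
#'
#' @param instr an \linkS4class{InstrumentSet}
#' @param family "ivw" (origin) or "egger" (intercept; needs >= 3 instruments)
#' @param effects "fixed" or "random"
#' @param ridgeEps initial ridge added to the LD diagonal (escalates tenfold
#'   up to 1e-4 before a conditioning error)
#' @return an \linkS4class{MREstimate}
#' @export
glsFit <- function(instr, family = c("ivw", "egger"),
                   effects = c("fixed", "random"), ridgeEps = 1e-8) {
  family <- match.arg(family)
  effects <- match.arg(effects)
  p <- instr@pairs
  n <- nrow(p)
  if (n < 1) pkgError("empty_instrument_error", "no instruments")
  if (family == "egger" && n < 3)
    pkgError("insufficient_instruments_error", "Egger needs >= 3 instruments")
  bx <- p$bx; by <- p$by; sy <- p$sy
  R <- instr@ld@r
  if (family == "egger") {
    flip <- sign(bx)
    flip[flip == 0] <- 1
    bx <- bx * flip
    by <- by * flip
    R <- R * tcrossprod(flip)          # orientation flips LD signs too
    X <- cbind(intercept = 1, slope = bx)
  } else {
    X <- cbind(slope = bx)
  }
  fit <- glsCore(X, by, sy, R, ridgeEps)
  k <- ncol(X)
  infl <- if (effects == "random" && fit$df > 0) max(1, fit$q / fit$df) else 1
  v <- fit$vcov * infl
  slope_i <- k                          # slope is the last column
  beta <- fit$coef[slope_i]
  se <- sqrt(v[slope_i, slope_i])
  intercept <- if (family == "egger") fit$coef[1] else NA_real_
  interceptSE <- if (family == "egger") sqrt(v[1, 1]) else NA_real_
  z <- qnorm(0.975)
  new("MREstimate", beta = beta, se = se, ciLow = beta - z * se,
      ciHigh = beta + z * se, pvalue = zPvalue(beta, se), or = exp(beta),
      intercept = intercept, interceptSE = interceptSE,
      q = fit$q, qDf = fit$df,
      qPvalue = if (is.na(fit$qPvalue)) NA_real_ else fit$qPvalue,
      nSnps = n, family = family, effects = effects, unit = instr@unit)
}

#' Cochran's Q heterogeneity statistic and per-variant contributions
#'
#' Q = (by - X bhat)' Sigma^-1 (by - X bhat) with df = n_snps - parameters.
#' Contributions are the squared whitened residuals, which under identity LD
#' reduce to the per-variant quadratic-form shares.
#'
#' @param instr an \linkS4class{InstrumentSet}
#' @param fit an \linkS4class{MREstimate} produced on \code{instr}
#' @return list with q, df, pvalue, contributions (named by variant) and
#'   leverage (whitened hat-matrix diagonal)
#' @export
cochranQ <- function(instr, fit) {
  p <- instr@pairs
  n <- nrow(p)
  if (n - (if (fit@family == "egger") 2 else 1) <= 0)
    pkgError("undefined_heterogeneity_error",
             "Q undefined: no residual degrees of freedom")
  bx <- p$bx; by <- p$by; sy <- p$sy
  R <- instr@ld@r
  if (fit@family == "egger") {
    flip <- sign(bx); flip[flip == 0] <- 1
    bx <- bx * flip; by <- by * flip; R <- R * tcrossprod(flip)
    X <- cbind(1, bx)
    coefs <- c(fit@intercept, fit@beta)
  } else {
    X <- cbind(bx)
    coefs <- fit@beta
  }
  sol <- ldSolve(R)
  Lt <- sol$chol
  resid_w <- backsolve(Lt, (by - drop(X %*% coefs)) / sy, transpose = TRUE)
  q <- sum(resid_w^2)
  df <- n - ncol(X)
  contrib <- setNames(drop(resid_w)^2, p$variant)
  Xs <- X / sy
  Xw <- backsolve(Lt, Xs, transpose = TRUE)
  H <- Xw %*% solve(crossprod(Xw)) %*% t(Xw)
  list(q = q, df = df, pvalue = pchisq(q, df, lower.tail = FALSE),
       contributions = contrib, leverage = setNames(diag(H), p$variant))
}

## subset an InstrumentSet to the given variant ids (keeping order)
subsetInstruments <- function(instr, keep) {
  p <- instr@pairs
  p <- p[p$variant %in% keep, , drop = FALSE]
  ids <- p$variant
  InstrumentSet(p, LDMatrix(instr@ld@r[ids, ids, drop = FALSE], ids),
                unit = instr@unit, exposureTrait = instr@exposureTrait,
                outcomeTrait = instr@outcomeTrait)
}

#' Remove heterogeneity outliers and high-leverage instruments
#'
#' Iteratively refits the currently selected model (see
#' \code{\link{selectModel}}) and removes the worst-contributing variant while
#' the global Q p-value is below \code{qAlpha}; afterwards a single sweep
#' removes variants whose whitened hat-matrix leverage exceeds
#' \code{leverageMult} times the mean leverage. The leverage sweep is not
#' iterated: leverage is proportional to the squared instrument effect, so
#' re-testing against a freshly shrunken mean would cascade through perfectly
#' well-behaved strong instruments. Never prunes below 1 variant (IVW floor)
#' or below 3 when the selected family is Egger.
#'
#' @param instr an \linkS4class{InstrumentSet} with >= 2 instruments
#' @param qAlpha heterogeneity p-value threshold (default 0.001)
#' @param leverageMult leverage multiplier (default 3)
#' @return the pruned \linkS4class{InstrumentSet}; attribute \code{removed}
#'   lists the removed variant ids
#' @export
pruneOutliers <- function(instr, qAlpha = 0.001, leverageMult = 3) {
  stopifnot(nrow(instr@pairs) >= 2)
  removed <- character(0)
  cur <- instr
  ## phase 1: iterative heterogeneity pruning against the selected model
  repeat {
    n <- nrow(cur@pairs)
    fit <- selectModel(cur)
    floor_n <- if (fit@family == "egger") 3L else 1L
    if (n <= floor_n) break
    qc <- tryCatch(cochranQ(cur, fit), error = function(e) NULL)
    if (is.null(qc) || is.na(qc$pvalue) || qc$pvalue >= qAlpha) break
    worst <- names(which.max(qc$contributions))
    removed <- c(removed, worst)
    cur <- subsetInstruments(cur, setdiff(cur@pairs$variant, worst))
  }
  ## phase 2: one leverage sweep at the post-pruning fit
  fit <- selectModel(cur)
  floor_n <- if (fit@family == "egger") 3L else 1L
  qc <- tryCatch(cochranQ(cur, fit), error = function(e) NULL)
  if (!is.null(qc)) {
    high <- names(sort(qc$leverage[qc$leverage >
                                     leverageMult * mean(qc$leverage)],
                       decreasing = TRUE))
    for (v in high) {
      if (nrow(cur@pairs) <= floor_n) break
      removed <- c(removed, v)
      cur <- subsetInstruments(cur, setdiff(cur@pairs$variant, v))
    }
  }
  attr(cur, "removed") <- removed
  cur
}

#' Rucker-type model selection between IVW and Egger, fixed and random effects
#'
#' Computes Q under the IVW and (when >= 3 instruments) Egger fits; if
#' Q_ivw - Q_egger exceeds the chi-square(1) critical value at
#' \code{alphaFamily}, directional pleiotropy is declared and the Egger
#' family is chosen, otherwise IVW. Within the chosen family, random effects
#' is used iff that family's Q p-value is below \code{alphaQ}.
#'
#' The family switch is a one-degree-of-freedom pretest; draws falsely
#' selected into the Egger family carry badly calibrated post-selection
#' intervals, so the default family level is 1 percent (the fixed-vs-random
#' decision stays at 5 percent), keeping the selected-model confidence
#' interval near nominal coverage while retaining power against genuine
#' directional pleiotropy.
#'
#' @param instr an \linkS4class{InstrumentSet}
#' @param alphaQ significance level for the fixed-vs-random decision
#'   (default 0.05)
#' @param alphaFamily significance level for the IVW-vs-Egger Q-difference
#'   decision (default 0.01)
#' @return the selected \linkS4class{MREstimate}
#' @export
selectModel <- function(instr, alphaQ = 0.05, alphaFamily = 0.01) {
  n <- nrow(instr@pairs)
  ivw <- glsFit(instr, "ivw", "fixed")
  family <- "ivw"
  if (n >= 3) {
    egger <- glsFit(instr, "egger", "fixed")
    crit <- stats::qchisq(1 - alphaFamily, df = 1)
    if ((ivw@q - egger@q) > crit) family <- "egger"
  }
  chosen <- if (family == "ivw") ivw else egger
  effects <- if (!is.na(chosen@qPvalue) && chosen@qPvalue < alphaQ)
    "random" else "fixed"
  if (effects == "random") chosen <- glsFit(instr, family, "random")
  chosen
}

#' Multivariable MR by multi-column GLS
#'
#' Regresses the outcome effects on several exposures' effect columns jointly
#' (no intercept) under the same LD-aware error covariance as
#' \code{\link{glsFit}}. The joint heterogeneity Q is reported as evidence of
#' horizontal pleiotropy beyond the modeled exposures.
#'
#' @param exposuresBeta matrix (variants x exposures) of exposure effects,
#'   column names are the exposure labels
#' @param by,sy outcome effects and SEs aligned to the rows
#' @param ld \linkS4class{LDMatrix} over the same ordered variants
#' @param effects "fixed" or "random"
#' @param unit analysis-unit label
#' @return an \linkS4class{MVMREstimate}
#' @export
mvmrFit <- function(exposuresBeta, by, sy, ld, effects = c("fixed", "random"),
                    unit = "genome-wide") {
  effects <- match.arg(effects)
  X <- as.matrix(exposuresBeta)
  k <- ncol(X)
  n <- length(by)
  if (n < k + 1)
    pkgError("insufficient_instruments_error",
             sprintf("MVMR needs >= %d instruments, got %d", k + 1, n))
  fit <- glsCore(X, by, sy, ld@r)
  infl <- if (effects == "random" && fit$df > 0) max(1, fit$q / fit$df) else 1
  v <- fit$vcov * infl
  se <- sqrt(diag(v))
  z <- qnorm(0.975)
  est <- data.frame(exposure = colnames(X), beta = fit$coef, se = se,
                    ci_low = fit$coef - z * se, ci_high = fit$coef + z * se,
                    pvalue = zPvalue(fit$coef, se), or = exp(fit$coef),
                    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  new("MVMREstimate", estimates = est, q = fit$q, qDf = fit$df,
      qPvalue = fit$qPvalue, nSnps = n, unit = unit)
}
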