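test_that("waldRatio matches hand arithmetic and the delta-method simulation", {
  w <- waldRatio(0.5, 0, 0.2, 0.05)
  expect_equal(w$ratio, 0.4)
  expect_equal(w$se, 0.1)
  expect_equal(waldRatio(1, 0.1, 0, 0.05)$ratio, 0)
  expect_error(waldRatio(0, 0.1, 0.2, 0.05),
               class = "degenerate_instrument_error")
  ## Monte-Carlo oracle for the first-order se, in the regime where the
  ## linearization is valid (exposure coefficient of variation below ~10%)
  set.seed(1)
  bxs <- rnorm(1e6, 0.5, 0.04)
  bys <- rnorm(1e6, 0.2, 0.05)
  mc <- sd(bys / bxs)
  expect_lt(abs(waldRatio(0.5, 0.04, 0.2, 0.05)$se - mc) / mc, 0.05)
})

test_that("single-variant GLS reduces to the Wald ratio", {
  instr <- makeInstr(bx = 0.5, sx = 0, by = 0.2, sy = 0.05)
  fit <- glsFit(instr, "ivw", "fixed")
  w <- waldRatio(0.5, 0, 0.2, 0.05)
  expect_equal(fit@beta, w$ratio)
  expect_equal(fit@se, w$se)
  expect_equal(fit@nSnps, 1)
})

test_that("GLS under identity LD equals the closed-form IVW oracle to 1e-10", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:15, 1)
    bx <- rnorm(n, 0.1, 0.05)
    bx[abs(bx) < 0.01] <- 0.05
    by <- rnorm(n, 0.04, 0.02)
    sy <- runif(n, 0.005, 0.05)
    instr <- makeInstr(bx, 0.01, by, sy)
    fit <- glsFit(instr, "ivw", "fixed")
    o <- ivwOracle(bx, by, sy)
    expect_lt(abs(fit@beta - o$slope), 1e-10)
    expect_lt(abs(fit@se - o$se), 1e-10)
  }
})

test_that("perfectly duplicated instruments collapse to the single-variant fit", {
  R <- matrix(c(1, 1, 1, 1), 2)
  instr2 <- makeInstr(c(0.5, 0.5), 0.01, c(0.2, 0.2), c(0.05, 0.05), R = R)
  instr1 <- makeInstr(0.5, 0.01, 0.2, 0.05)
  f2 <- glsFit(instr2, "ivw", "fixed")
  f1 <- glsFit(instr1, "ivw", "fixed")
  expect_lt(abs(f2@beta - f1@beta), 1e-6)
})

test_that("estimates are equivariant under allele flips and exposure scaling", {
  set.seed(9)
  n <- 8
  bx <- rnorm(n, 0.1, 0.03)
  by <- 0.4 * bx + rnorm(n, 0, 0.01)
  sy <- rep(0.01, n)
  A <- matrix(rnorm(n * 40), 40, n)
  R <- cor(A)
  base <- glsFit(makeInstr(bx, 0.01, by, sy, R = R), "ivw", "fixed")
  ## flipping all effect alleles negates both betas and preserves LD signs
  flip <- glsFit(makeInstr(-bx, 0.01, -by, sy, R = R), "ivw", "fixed")
  expect_equal(flip@beta, base@beta)
  ## scaling the exposure by c scales the slope by 1/c
  sc <- glsFit(makeInstr(2 * bx, 0.02, by, sy, R = R), "ivw", "fixed")
  expect_equal(sc@beta, base@beta / 2)
})

test_that("random-effects SE never falls below fixed-effects SE", {
  for (s in 1:10) {
    set.seed(s)
    n <- 10
    bx <- rnorm(n, 0.1, 0.03)
    by <- 0.3 * bx + rnorm(n, 0, 0.03)   # overdispersed
    instr <- makeInstr(bx, 0.01, by, rep(0.01, n))
    ff <- glsFit(instr, "ivw", "fixed")
    fr <- glsFit(instr, "ivw", "random")
    expect_gte(fr@se, ff@se)
    if (n >= 3) {
      ef <- glsFit(instr, "egger", "fixed")
      er <- glsFit(instr, "egger", "random")
      expect_gte(er@se, ef@se)
    }
  }
})

test_that("Cochran's Q is zero for a perfect fit and flags planted outliers", {
  n <- 6
  bx <- seq(0.05, 0.3, length.out = n)
  by <- 0.4 * bx                        # identical Wald ratios
  instr <- makeInstr(bx, 0.01, by, rep(0.01, n))
  fit <- glsFit(instr, "ivw", "fixed")
  qc <- cochranQ(instr, fit)
  expect_lt(qc$q, 1e-18)
  expect_equal(qc$df, n - 1)
  ## a 10-SE outlier dominates the contributions
  by2 <- by
  by2[4] <- by[4] + 10 * 0.01
  instr2 <- makeInstr(bx, 0.01, by2, rep(0.01, n))
  fit2 <- glsFit(instr2, "ivw", "fixed")
  qc2 <- cochranQ(instr2, fit2)
  expect_equal(which.max(qc2$contributions), 4, ignore_attr = TRUE)
  expect_error(cochranQ(makeInstr(0.5, 0, 0.2, 0.05),
                        glsFit(makeInstr(0.5, 0, 0.2, 0.05))),
               class = "undefined_heterogeneity_error")
})

test_that("Q under the null has mean approximately equal to its df", {
  set.seed(11)
  n <- 10
  bx <- rnorm(n, 0.1, 0.02)
  sy <- rep(0.01, n)
  qs <- replicate(1000, {
    by <- 0.3 * bx + rnorm(n, 0, sy)
    instr <- makeInstr(bx, 0, by, sy)
    cochranQ(instr, glsFit(instr, "ivw", "fixed"))$q
  })
  df <- n - 1
  ## chi-square(df) mean check with a 4-sigma Monte-Carlo band
  expect_lt(abs(mean(qs) - df), 4 * sqrt(2 * df / 1000))
})

test_that("pruneOutliers removes exactly the planted pleiotropic variant", {
  set.seed(21)
  n <- 10
  bx <- runif(n, 0.08, 0.3)
  sy <- rep(0.01, n)
  by <- 0.4 * bx + rnorm(n, 0, 0.002)
  by[7] <- by[7] + 0.12                 # strongly pleiotropic
  instr <- makeInstr(bx, 0.005, by, sy)
  pruned <- pruneOutliers(instr)
  expect_equal(attr(pruned, "removed"), pairs(instr)$variant[7])
  expect_equal(nrow(pairs(pruned)), n - 1)
  ## a homogeneous, balanced set is returned unchanged
  by_h <- 0.4 * bx + rnorm(n, 0, 0.002)
  instr_h <- makeInstr(bx, 0.005, by_h, sy)
  pruned_h <- pruneOutliers(instr_h)
  expect_equal(nrow(pairs(pruned_h)), n)
  ## with two instruments the floor of one variant is respected
  i2 <- makeInstr(c(0.1, 0.2), 0.005, c(0.1, -0.1), c(0.01, 0.01))
  p2 <- pruneOutliers(i2)
  expect_gte(nrow(pairs(p2)), 1)
})

test_that("model selection keeps IVW under the null and finds pleiotropy", {
  ## under no pleiotropy the IVW family should win nearly always
  set.seed(31)
  n <- 20
  bx <- runif(n, 0.05, 0.3)
  sy <- rep(0.01, n)
  fams <- replicate(500, {
    by <- 0.3 * bx + rnorm(n, 0, sy)
    selectModel(makeInstr(bx, 0, by, sy))@family
  })
  expect_gte(mean(fams == "ivw"), 0.9)
  ## a common directional intercept drives the Egger choice, with power
  ## increasing in the number of instruments
  eggerRate <- function(n, reps = 200) {
    bx <- runif(n, 0.05, 0.3)
    sy <- rep(0.01, n)
    mean(replicate(reps, {
      by <- 0.05 + 0.3 * bx + rnorm(n, 0, sy)
      selectModel(makeInstr(bx, 0, by, sy))@family == "egger"
    }))
  }
  set.seed(32)
  r_small <- eggerRate(5)
  r_large <- eggerRate(40)
  expect_gt(r_large, r_small)
  expect_gt(r_large, 0.9)
  ## two instruments force the IVW family
  i2 <- makeInstr(c(0.1, 0.2), 0, c(0.05, 0.11), c(0.01, 0.01))
  expect_equal(selectModel(i2)@family, "ivw")
})

test_that("mvmrFit reduces to univariable GLS and detects collinearity", {
  set.seed(41)
  n <- 12
  bx <- rnorm(n, 0.15, 0.05)
  by <- 0.4 * bx + rnorm(n, 0, 0.01)
  sy <- rep(0.01, n)
  ld <- LDMatrix(diag(n), paste0("v", 1:n))
  X <- matrix(bx, ncol = 1, dimnames = list(NULL, "exp1"))
  mv <- mvmrFit(X, by, sy, ld)
  uv <- glsFit(makeInstr(bx, 0, by, sy), "ivw", "fixed")
  expect_equal(mv@estimates$beta, uv@beta)
  expect_equal(mv@estimates$se, uv@se)
  ## duplicated exposure column: exact rank deficiency
  X2 <- cbind(exp1 = bx, exp2 = bx)
  expect_error(mvmrFit(X2, by, sy, ld), class = "collinearity_error")
})

test_that("mvmrFit recovers two orthogonal exposure effects with nominal coverage", {
  set.seed(51)
  n <- 20
  theta <- c(0.5, -0.3)
  bx1 <- c(runif(10, 0.1, 0.3), rep(0, 10))
  bx2 <- c(rep(0, 10), runif(10, 0.1, 0.3))
  X <- cbind(e1 = bx1, e2 = bx2)
  sy <- rep(0.01, n)
  ld <- LDMatrix(diag(n), paste0("v", 1:n))
  hits <- replicate(500, {
    by <- drop(X %*% theta) + rnorm(n, 0, sy)
    mv <- mvmrFit(X, by, sy, ld)
    all(mv@estimates$ci_low <= theta & theta <= mv@estimates$ci_high)
  })
  expect_gte(mean(hits), 0.93 * 0.95)   # joint coverage of two 95% CIs
})
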