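## numeric-integration oracle for the dichotomized-Gaussian indicator
## correlation: P(Z1 < t1, Z2 < t2) under correlation rho by 1-D quadrature
binormCdf <- function(t1, t2, rho) {
  stats::integrate(function(z)
    pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
    -Inf, t1, rel.tol = 1e-10)$value
}

dichotCor <- function(p1, p2, rho) {
  t1 <- qnorm(p1); t2 <- qnorm(p2)
  p11 <- binormCdf(t1, t2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

test_that("generators are deterministic under a seed and vary across seeds", {
  cfg <- simConfig(nVariants = 15, nRef = 400, nCausal = 5, seed = 42)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(a$panel@dosages, b$panel@dosages)
  ga <- simulateGwas(a, cfg, mode = "summary")
  gb <- simulateGwas(b, cfg, mode = "summary")
  expect_identical(records(ga$outcome), records(gb$outcome))
  cfg2 <- simConfig(nVariants = 15, nRef = 400, nCausal = 5, seed = 43)
  c <- simulatePanel(cfg2)
  expect_false(identical(a$panel@dosages, c$panel@dosages))
  ## replication pairs are internally independent but reproducible
  p1 <- simulateReplicationPair(cfg)
  p2 <- simulateReplicationPair(cfg)
  expect_identical(records(p1$replication$outcome),
                   records(p2$replication$outcome))
  expect_false(identical(records(p1$discovery$outcome),
                         records(p1$replication$outcome)))
})

test_that("panel LD matches the AR(1) dichotomized-Gaussian theory", {
  ## rho = 0: off-diagonal dosage correlations are sampling noise
  cfg0 <- simConfig(nVariants = 10, nRef = 5000, rho = 0, nCausal = 3,
                    seed = 7)
  sim0 <- simulatePanel(cfg0)
  off <- abs(sim0$ld@r[upper.tri(sim0$ld@r)])
  expect_lt(mean(off), 0.05)
  ## rho = 0.9: adjacent-pair correlation tracks the numeric oracle
  cfg9 <- simConfig(nVariants = 10, nRef = 5000, rho = 0.9, nCausal = 3,
                    seed = 8)
  sim9 <- simulatePanel(cfg9)
  for (j in 1:9) {
    want <- dichotCor(sim9$maf[j], sim9$maf[j + 1], 0.9)
    expect_lt(abs(sim9$ld@r[j, j + 1] - want), 0.1)
  }
  ## the LD matrix satisfies its container invariants by construction
  expect_true(validObject(sim9$ld))
})

test_that("exposure SEs follow the 1/sqrt(2 n maf (1-maf)) asymptotics", {
  cfg <- simConfig(nVariants = 12, nRef = 800, nCausal = 4, nExposure = 10000,
                   nOutcome = 10000, seed = 9)
  sim <- simulatePanel(cfg)
  g <- simulateGwas(sim, cfg, mode = "individual")
  rec <- records(g$exposures[[1]])
  expected <- 1 / sqrt(rec$n * 2 * rec$eaf * (1 - rec$eaf))
  expect_lt(max(abs(rec$se - expected) / expected), 0.1)
})

test_that("summary and individual modes agree with each other and the truth", {
  cfg <- simConfig(nVariants = 15, nRef = 2000, nCausal = 5, h2 = 0.2,
                   nExposure = 20000, nOutcome = 20000, theta = 0.4,
                   rho = 0.5, seed = 10)
  sim <- simulatePanel(cfg)
  truth <- drugTargetMR:::simTruth(cfg, sim$ld, sim$maf)
  margAllele <- drop(truth$margX) / truth$sdg
  avg_s <- avg_i <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    gs <- simulateGwas(sim, cfg, mode = "summary",
                       seed = drugTargetMR:::childSeed(500, r))
    gi <- simulateGwas(sim, cfg, mode = "individual",
                       seed = drugTargetMR:::childSeed(600, r))
    avg_s <- avg_s + records(gs$exposures[[1]])$beta / reps
    avg_i <- avg_i + records(gi$exposures[[1]])$beta / reps
  }
  ## both modes center on the same LD-projected marginal effects
  expect_lt(max(abs(avg_s - margAllele)), 0.04)
  expect_lt(max(abs(avg_i - margAllele)), 0.04)
})

test_that("a null variant in LD inherits r times the causal marginal effect", {
  cfg <- simConfig(nVariants = 6, nRef = 4000, rho = 0.8, nCausal = 1,
                   seed = 11)
  B <- matrix(0, 6, 1)
  B[3, 1] <- 0.2
  cfg$causalEffects <- B
  sim <- simulatePanel(cfg)
  truth <- drugTargetMR:::simTruth(cfg, sim$ld, sim$maf)
  ## standardized marginal effect of the null neighbour = r * causal effect
  r34 <- sim$ld@r[3, 4]
  expect_equal(unname(truth$margX[4, 1]), r34 * 0.2, tolerance = 1e-10)
})

test_that("score and glm logistic paths agree for modest effects", {
  cfg <- simConfig(nVariants = 8, nRef = 800, nCausal = 3, h2 = 0.3,
                   nExposure = 6000, nOutcome = 6000, theta = 0.5,
                   caseFraction = 0.3, seed = 12)
  sim <- simulatePanel(cfg)
  g1 <- simulateGwas(sim, cfg, mode = "individual", binaryMethod = "score",
                     seed = 77)
  g2 <- simulateGwas(sim, cfg, mode = "individual", binaryMethod = "glm",
                     seed = 77)
  b1 <- records(g1$outcome)$beta
  b2 <- records(g2$outcome)$beta
  small <- abs(b2) < 0.3 & abs(b2) > 0.02
  expect_true(any(small))
  expect_lt(max(abs(b1[small] - b2[small]) / abs(b2[small])), 0.02)
})

test_that("null architecture gives nominal z-test size; effects are recovered", {
  ## theta = 0, no pleiotropy: |z| < 1.96 in about 95% of repetitions
  cfg0 <- simConfig(nVariants = 10, nRef = 1500, nCausal = 10, theta = 0,
                    nExposure = 50000, nOutcome = 50000, rho = 0.5, seed = 13)
  sim0 <- simulatePanel(cfg0)
  inside <- replicate(500, {
    g <- simulateGwas(sim0, cfg0, mode = "summary",
                      seed = drugTargetMR:::childSeed(700, sample.int(1e6, 1)))
    fit <- glsFit(instrFromSim(g, sim0$ld), "ivw", "fixed")
    abs(fit@beta / fit@se) < qnorm(0.975)
  })
  expect_gte(mean(inside), 0.92)
  expect_lte(mean(inside), 0.98)
  ## theta = 0.4 with 20 causal variants at n = 50k: median IVW within 0.05
  cfg4 <- simConfig(nVariants = 20, nRef = 1500, nCausal = 20, theta = 0.4,
                    nExposure = 50000, nOutcome = 50000, rho = 0.5, seed = 14)
  sim4 <- simulatePanel(cfg4)
  est <- replicate(500, {
    g <- simulateGwas(sim4, cfg4, mode = "summary",
                      seed = drugTargetMR:::childSeed(800, sample.int(1e6, 1)))
    glsFit(instrFromSim(g, sim4$ld), "ivw", "fixed")@beta
  })
  expect_lt(abs(median(est) - 0.4), 0.05)
})

test_that("replication power and null concordance behave as designed", {
  set.seed(15)
  cfg <- simConfig(nVariants = 10, nRef = 1500, nCausal = 10, theta = 0.4,
                   rho = 0.5, seed = 15)
  sim <- simulatePanel(cfg)
  repCfg <- cfg
  repCfg$nExposure <- 33029
  repCfg$nOutcome <- 296525
  repCfg$caseFraction <- 0.1165
  concordant <- replicate(100, {
    gd <- simulateGwas(sim, cfg, mode = "summary",
                       seed = sample.int(1e6, 1))
    gr <- simulateGwas(sim, repCfg, mode = "summary",
                       seed = sample.int(1e6, 1))
    fd <- glsFit(instrFromSim(gd, sim$ld), "ivw", "fixed")
    fr <- glsFit(instrFromSim(gr, sim$ld), "ivw", "fixed")
    sign(fd@beta) == sign(fr@beta)
  })
  expect_gte(mean(concordant), 0.95)
  ## under the null, direction agreement is a coin flip
  cfg0 <- cfg
  cfg0$theta <- 0
  flips <- replicate(400, {
    gd <- simulateGwas(sim, cfg0, mode = "summary", seed = sample.int(1e6, 1))
    gr <- simulateGwas(sim, cfg0, mode = "summary", seed = sample.int(1e6, 1))
    fd <- glsFit(instrFromSim(gd, sim$ld), "ivw", "fixed")
    fr <- glsFit(instrFromSim(gr, sim$ld), "ivw", "fixed")
    sign(fd@beta) == sign(fr@beta)
  })
  expect_gt(mean(flips), 0.38)
  expect_lt(mean(flips), 0.62)
})
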