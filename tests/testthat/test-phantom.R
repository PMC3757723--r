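test_that("template labels partition the grid and are deterministic", {
  tpl <- makeTemplatePhantom(c(48, 48, 48))
  counts <- table(factor(labelVolume(tpl), levels = 0:4))
  expect_identical(sum(counts), 110592L)
  expect_true(all(counts > 0))
  tpl2 <- makeTemplatePhantom(c(48, 48, 48))
  expect_identical(intensityVolume(tpl), intensityVolume(tpl2))
  expect_identical(labelVolume(tpl), labelVolume(tpl2))
})

test_that("label-2 count matches an independent voxel-by-voxel ellipsoid scan", {
  tpl <- makeTemplatePhantom(c(48, 48, 48))
  geo <- tpl@geometry
  # brute-force oracle: scan every voxel against the raw inequalities
  n2 <- 0L
  for (k in 0:47) for (j in 0:47) for (i in 0:47) {
    x <- c(i, j, k) - geo$center
    inWM <- sum((x / geo$wmRadii)^2) <= 1
    inVent <- sum((x / geo$ventRadii)^2) <= 1
    if (inWM && !inVent) n2 <- n2 + 1L
  }
  expect_identical(sum(labelVolume(tpl) == 2L), n2)
})

test_that("invalid geometry is rejected naming the axis", {
  expect_error(makeTemplatePhantom(c(48, 48, 48),
                                   geometry = list(radii = c(30, 18, 17))),
               "axis 1")
  expect_error(makeTemplatePhantom(c(16, 48, 48)), "32")
})

test_that("genotype doses follow Hardy-Weinberg proportions", {
  expect_identical(simulateGenotypes(100, maf = 0, seed = 1),
                   rep(0L, 100) + 0L)
  expect_error(simulateGenotypes(10, maf = 0.7), "maf")
  n <- 1e5
  doses <- simulateGenotypes(n, maf = 0.31, seed = 42)
  pTT <- 0.31^2
  se <- sqrt(pTT * (1 - pTT) / n)
  expect_lt(abs(mean(doses == 2) - pTT), 3 * se)
  # independent multinomial oracle under the same seed policy
  set.seed(42)
  oracle <- drop(stats::rmultinom(1, n, c(0.69^2, 2 * 0.69 * 0.31, 0.31^2)))
  empirical <- tabulate(doses + 1L, 3L)
  expect_true(all(abs(empirical - oracle) / n < 3 * sqrt(0.5 * 0.5 / n) * 3))
  # frequencies converge: chi-square GOF non-significant in >= 19/20 seeds
  pvals <- vapply(1:20, function(s) {
    d <- simulateGenotypes(n, 0.31, seed = s)
    suppressWarnings(stats::chisq.test(
      tabulate(d + 1L, 3L), p = c(0.69^2, 2 * 0.69 * 0.31, 0.31^2))$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19L)
  expect_identical(simulateGenotypes(50, 0.31, seed = 9),
                   simulateGenotypes(50, 0.31, seed = 9))
})

test_that("covariates calibrate homocysteine to the genotype group means", {
  doses <- rep(0:2, each = 4000)
  cov <- simulateCovariates(doses, effectSpec(), seed = 5)
  m2 <- mean(cov$hcy[cov$dose == 2])
  se2 <- sd(cov$hcy[cov$dose == 2]) / sqrt(4000)
  expect_lt(abs(m2 - 11.7), 3 * se2)        # TT group mean
  expect_true(all(cov$age >= 55 & cov$age <= 95))
  expect_true(all(cov$hcy > 0))
  # noiseless limit is exact
  cov0 <- simulateCovariates(0:2, effectSpec(hcySD = 0), seed = 1)
  expect_equal(cov0$hcy, 10.2 + 0.75 * (0:2))
  # determinism
  expect_identical(simulateCovariates(doses[1:50], seed = 3),
                   simulateCovariates(doses[1:50], seed = 3))
})

test_that("null subject reproduces the template exactly", {
  tpl <- smallTemplate()
  s <- synthesizeSubjectVolume(tpl, subjectRecord(dose = 0), quietEffect(),
                               seed = 1)
  expect_identical(s$volume, intensityVolume(tpl))
  expect_equal(max(abs(jacobian(s$groundTruthJacobian) - 1)), 0)
})

test_that("implanted Jacobian equals the dose-scaled contraction in the target", {
  tpl <- smallTemplate()
  s <- synthesizeSubjectVolume(tpl,
                               subjectRecord(dose = 2, hcy = 11.7),
                               quietEffect(percentPerAllele = -6,
                                           mediationFraction = 0),
                               seed = 1)
  wm <- labelVolume(tpl) == 2L
  expect_equal(mean(jacobian(s$groundTruthJacobian)[wm]), 0.88,
               tolerance = 1e-6)
  expect_true(all(jacobian(s$groundTruthJacobian) > 0))
})

test_that("ground-truth Jacobian conserves mass against warped-label counting", {
  tpl <- makeTemplatePhantom(c(48, 48, 48))
  tissue <- labelVolume(tpl) > 0
  for (dose in c(1L, 2L)) {
    s <- synthesizeSubjectVolume(tpl,
                                 subjectRecord(dose = dose,
                                               hcy = 10.2 + 0.75 * dose),
                                 quietEffect(percentPerAllele = -6),
                                 seed = 2)
    integral <- sum(jacobian(s$groundTruthJacobian)[tissue])
    counted <- sum(s$warpedLabels > 0)
    expect_lt(abs(integral - counted) / integral, 0.02)
  }
})

test_that("extreme contractions are rejected as non-invertible", {
  tpl <- smallTemplate()
  expect_error(synthesizeSubjectVolume(tpl, subjectRecord(dose = 2),
                                       quietEffect(percentPerAllele = -50),
                                       seed = 1),
               "-100|non-invertible|non-monotone")
})

test_that("follow-up pairs implant the annualized progression", {
  tpl <- smallTemplate()
  eff <- quietEffect(percentPerAllele = 0, annualPercentPerAllele = -1.5)
  # dose 0: follow-up equals baseline exactly in the noiseless limit
  p0 <- synthesizeFollowupPair(tpl, subjectRecord(dose = 0, interval = 12),
                               eff, seed = 1)
  expect_identical(p0$baseline$volume, p0$followup$volume)
  # dose 2 at 12 months: follow-up/baseline core Jacobian 0.97
  p2 <- synthesizeFollowupPair(tpl,
                               subjectRecord(dose = 2, hcy = 11.7,
                                             interval = 12),
                               eff, seed = 1)
  expect_equal(p2$followup$coreJacobian / p2$baseline$coreJacobian, 0.97,
               tolerance = 1e-10)
  # 18-month interval, dose 1: -2.25% before annualization
  p18 <- synthesizeFollowupPair(tpl,
                                subjectRecord(dose = 1, hcy = 10.95,
                                              interval = 18),
                                eff, seed = 1)
  expect_equal((p18$followup$coreJacobian / p18$baseline$coreJacobian - 1) * 100,
               -2.25, tolerance = 1e-10)
})

test_that("follow-up intervals reproduce the printed frequency table", {
  iv <- sampleFollowupInterval(5000, seed = 3)
  expect_true(all(iv %in% c(10, 12, 13, 14, 15, 16)))
  expect_equal(mean(iv == 13), 176 / 307, tolerance = 0.03)
  expect_error(synthesizeFollowupPair(smallTemplate(),
                                      subjectRecord(dose = 0, interval = 30),
                                      quietEffect(), seed = 1),
               "\\[6, 24\\]")
})

test_that("full mediation makes volume change independent of dose given hcy", {
  # partial regression on ground-truth core Jacobians, analytic volumes
  doses <- rep(0:2, each = 120)
  cov <- simulateCovariates(doses, effectSpec(mediationFraction = 1),
                            seed = 11)
  eff <- quietEffect(percentPerAllele = -6, mediationFraction = 1)
  pct <- vapply(seq_len(nrow(cov)), function(i)
    (phantomTBM:::impliedCoreJacobian(cov[i, ], eff) - 1) * 100, numeric(1))
  fit <- lm(pct ~ dose + hcy, data = cbind(cov, pct = pct))
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf["dose", "Estimate"]), 3 * cf["dose", "Std. Error"] + 1e-8)
  # and the unadjusted dose slope matches the calibrated -6 in expectation
  fit0 <- lm(pct ~ dose, data = cbind(cov, pct = pct))
  expect_equal(unname(coef(fit0)["dose"]), -6,
               tolerance = 3 * summary(fit0)$coefficients["dose", 2] / 6)
})

test_that("synthesis is reproducible under a fixed seed", {
  tpl <- smallTemplate()
  eff <- effectSpec()      # noise and nuisance warp on
  rec <- subjectRecord(id = "R1", dose = 1, hcy = 10.95)
  a <- synthesizeSubjectVolume(tpl, rec, eff, seed = 21)
  b <- synthesizeSubjectVolume(tpl, rec, eff, seed = 21)
  expect_identical(a$volume, b$volume)
  c <- synthesizeSubjectVolume(tpl, rec, eff, seed = 22)
  expect_false(identical(a$volume, c$volume))
})
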