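test_that("genotype percentages reproduce the printed cohort tables", {
  expect_equal(unname(genotypePercentages(149, 157, 53)), c(14.8, 43.7))
  expect_equal(unname(genotypePercentages(16, 29, 6))[1], 11.8)
  expect_equal(unname(genotypePercentages(10, 0, 0)), c(0, 0))
  expect_error(genotypePercentages(0, 0, 0), "positive")
})

test_that("rounding agrees with exact rational arithmetic", {
  set.seed(2)
  for (i in 1:1000) {
    cnt <- sample(0:500, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    got <- genotypePercentages(cnt[1], cnt[2], cnt[3])
    exactTT <- 100 * cnt[3] / sum(cnt)
    # round-half-away-from-zero oracle via integer arithmetic
    oracle <- floor(exactTT * 10 + 0.5) / 10
    expect_identical(unname(got["percent_tt"]), oracle)
  }
})

test_that("sex-by-genotype chi-square matches the printed cohort value", {
  # 92/57, 103/54, 36/17 males/females across CC, CT, TT
  r <- contingencyChi2(matrix(c(92, 57, 103, 54, 36, 17), 3, 2,
                              byrow = TRUE))
  expect_equal(round(r$chi2, 1), 0.8)
  expect_identical(r$df, 2L)
  expect_gt(r$p, 0.6)
})

test_that("chi-square follows the marginal-expectation hand computation", {
  tab <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  r <- contingencyChi2(tab)
  expect_equal(r$chi2, hand, tolerance = 1e-12)
  expect_identical(r$df, 1L)
  # invariant to transposition
  expect_equal(contingencyChi2(t(tab))$chi2, r$chi2)
  # identical row proportions give exactly zero
  expect_equal(contingencyChi2(matrix(c(10, 20, 20, 40), 2, byrow = TRUE))$chi2,
               0, tolerance = 1e-12)
  expect_error(contingencyChi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("one-way ANOVA equals t-squared for two groups", {
  set.seed(13)
  for (i in 1:100) {
    g <- rep(c("A", "B"), c(15, 12))
    v <- rnorm(27)
    a <- groupAnova(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(a$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("ANOVA F is near 1 under label permutation", {
  set.seed(3)
  v <- rnorm(90)
  fs <- vapply(1:100, function(i)
    groupAnova(v, sample(rep(c("CC", "CT", "TT"), each = 30)))$F, numeric(1))
  expect_lt(abs(mean(fs) - 1), 0.3)
  expect_error(groupAnova(rnorm(5), c("A", "A", "A", "A", "B")),
               "at least 2")
})

test_that("ANOVA power on the homocysteine shift matches the noncentral-F oracle", {
  # group sizes and dose-dependent shift as in the 359-subject table
  ns <- c(149, 157, 53)
  mus <- 10.2 + 0.75 * (0:2)
  sdv <- 2.4
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    g <- rep(c("CC", "CT", "TT"), ns)
    v <- rep(mus, ns) + rnorm(sum(ns), 0, sdv)
    groupAnova(v, g)$p < 0.01
  }, logical(1))
  # closed-form power of the one-way F test at these group means
  gm <- sum(ns * mus) / sum(ns)
  lambda <- sum(ns * (mus - gm)^2) / sdv^2
  power <- 1 - pf(qf(0.99, 2, sum(ns) - 3), 2, sum(ns) - 3, ncp = lambda)
  se <- sqrt(power * (1 - power) / 100)
  expect_lt(abs(mean(hits) - power), 3 * se + 0.01)
  expect_gt(mean(hits), 0.8)     # the shift is reliably detected
})

test_that("white-matter volume regression recovers exact constructions", {
  set.seed(6)
  n <- 60
  r <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  dose = sample(0:2, n, TRUE), age = rnorm(n, 75, 7),
                  sex = rbinom(n, 1, 0.6), stringsAsFactors = FALSE)
  vols <- data.frame(left = 250 - 5 * r$dose, right = 240 - 5 * r$dose)
  fit <- wmVolumeRegression(r, vols)
  expect_equal(fit$left$beta, -5, tolerance = 1e-10)
  expect_lt(fit$left$p, 1e-12)
  expect_equal(fit$right$beta, -5, tolerance = 1e-10)
  expect_error(wmVolumeRegression(r, vols[1:10, ]), "align")
})

test_that("null volume regressions give uniform p-values", {
  ps <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    n <- 50
    r <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    dose = sample(0:2, n, TRUE), age = rnorm(n, 75, 7),
                    sex = rbinom(n, 1, 0.6), stringsAsFactors = FALSE)
    vols <- data.frame(left = rnorm(n, 250, 20), right = rnorm(n, 240, 20))
    wmVolumeRegression(r, vols)$left$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("demographics table reports SE = SD/sqrt(n) and the expected tests", {
  doses <- rep(0:2, c(60, 60, 30))
  cov <- simulateCovariates(doses, effectSpec(), seed = 20)
  demo <- demographicsTable(cov)
  tab <- demo$table
  ageRow <- tab[tab$measure == "age", ]
  byHand <- sd(cov$age[cov$dose == 0]) / sqrt(60)
  expect_equal(ageRow$se_cc, byHand, tolerance = 1e-12)
  expect_false(is.null(demo$sexTest))
  # single group present: no tests, warning
  solo <- cov[cov$dose == 0, ]
  expect_warning(d1 <- demographicsTable(solo), "fewer than 2")
  expect_true(all(is.na(d1$table$F)))
})

test_that("simulated cohorts show the printed pattern of significance", {
  # homocysteine row significant, age row not, in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    doses <- simulateGenotypes(355, 0.31, seed = s)
    cov <- simulateCovariates(doses, effectSpec(), seed = s + 500)
    demo <- suppressWarnings(demographicsTable(cov))
    tab <- demo$table
    hcyP <- tab$p[tab$measure == "hcy"]
    ageP <- tab$p[tab$measure == "age"]
    !is.na(hcyP) && hcyP < 0.05 && !is.na(ageP) && ageP > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("label volumes track the implanted deficit end to end", {
  # analytic warped labels: dose shrinks measured WM volume
  tpl <- smallTemplate()
  hits <- vapply(1:20, function(s) {
    doses <- simulateGenotypes(120, 0.31, seed = s + 40)
    cov <- simulateCovariates(doses, effectSpec(), seed = s + 140)
    eff <- quietEffect(percentPerAllele = -6, mediationFraction = 0)
    wl <- lapply(seq_len(nrow(cov)), function(i)
      synthesizeSubjectVolume(tpl, cov[i, ], eff, seed = s)$warpedLabels)
    vols <- labelVolumesCC(wl, voxelSize(tpl))
    fit <- wmVolumeRegression(cov, vols)
    fit$left$beta < 0 && fit$left$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 16L)
})
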