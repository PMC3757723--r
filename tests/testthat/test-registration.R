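test_that("self-registration yields near-zero fields across configs", {
  tpl <- smallTemplate()
  v <- intensityVolume(tpl)
  for (cfg in list(registrationConfig(),
                   registrationConfig(nLevels = 2L, itersPerLevel = c(40L, 20L)),
                   registrationConfig(symmetric = TRUE,
                                      itersPerLevel = c(30L, 20L, 10L)))) {
    f <- registerNonlinear(v, v, cfg)
    expect_lt(max(abs(displacement(f))), 0.2)
  }
})

test_that("registration similarity is non-increasing within each level", {
  tpl <- smallTemplate()
  s <- synthesizeSubjectVolume(tpl, subjectRecord(dose = 2, hcy = 11.7),
                               quietEffect(percentPerAllele = -5), seed = 4)
  f <- registerNonlinear(s$volume, tpl, registrationConfig())
  for (tr in attr(f, "ssdTrace"))
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
})

test_that("demons recovers an implanted -10% contraction within 0.03", {
  tpl <- makeTemplatePhantom(c(48, 48, 48))
  s <- synthesizeSubjectVolume(tpl, subjectRecord(dose = 1, hcy = 10.95),
                               quietEffect(percentPerAllele = -10), seed = 8)
  f <- registerNonlinear(s$volume, tpl, registrationConfig())
  jm <- jacobianDeterminant(f)
  wm <- labelVolume(tpl) == 2L
  truth <- mean(jacobian(s$groundTruthJacobian)[wm])
  expect_lt(abs(mean(jacobian(jm)[wm]) - truth), 0.03)
  # accepted fields have positive Jacobians on the interior
  expect_true(all(jacobian(jm)[phantomTBM:::interiorMask(dim(wm))] > 0))
})

test_that("symmetric mode is at least 2x more inverse-consistent", {
  tpl <- midTemplate()
  s <- synthesizeSubjectVolume(tpl, subjectRecord(dose = 2, hcy = 11.7),
                               effectSpec(percentPerAllele = -8,
                                          nuisanceWarpMM = 0.4,
                                          noiseSD = 0.01),
                               seed = 3)
  asym <- registerNonlinear(s$volume, tpl, registrationConfig(), both = TRUE)
  sym <- registerNonlinear(s$volume, tpl,
                           registrationConfig(symmetric = TRUE), both = TRUE)
  iceA <- inverseConsistencyError(asym$forward, asym$backward)
  iceS <- inverseConsistencyError(sym$forward, sym$backward)
  expect_lt(iceS * 2, iceA)
})

test_that("warpVolume handles identity, pure translation, and inversion", {
  tpl <- smallTemplate()
  v <- intensityVolume(tpl)
  d <- dim(v)
  expect_identical(warpVolume(v, constantField(d)), v)
  shifted <- warpVolume(v, constantField(d, c(1, 0, 0)))
  expect_equal(shifted[1:(d[1] - 1), , ], v[2:d[1], , ])
  expect_error(warpVolume(v[1:10, , ], constantField(d)), "grid")
  # warp then inverse-warp through the numerical inverse
  f <- smoothRandomField(d, amplitude = 0.6, sigma = 3, seed = 5)
  vs <- phantomTBM:::smooth3D(v, 1)
  w <- warpVolume(vs, f)
  back <- warpVolume(w, invertField(f))
  interior <- phantomTBM:::interiorMask(d, 3L)
  expect_lt(mean(abs(back - vs)[interior]) / diff(range(vs)), 0.02)
})

test_that("inverse consistency error is zero for exact inverse constants", {
  d <- c(24L, 24L, 24L)
  fwd <- constantField(d, c(1.5, -0.5, 2))
  bwd <- constantField(d, c(-1.5, 0.5, -2))
  expect_equal(inverseConsistencyError(fwd, bwd), 0)
  expect_equal(inverseConsistencyError(constantField(d), constantField(d)), 0)
  # numerically inverted smooth field: residual well under 0.1 voxel
  f <- smoothRandomField(d, amplitude = 0.5, sigma = 2, seed = 7)
  expect_lt(inverseConsistencyError(f, invertField(f)), 0.1)
})

test_that("affine registration recovers known shifts and scales", {
  tpl <- midTemplate()
  v <- intensityVolume(tpl)
  self <- registerAffine(v, v, dof = 12)
  expect_lt(max(abs(self$t)), 0.1)
  expect_lt(max(abs(self$A - diag(3))), 0.01)
  # translated copy: content moved by -(3,-2,1) means transform t = (3,-2,1)
  d <- dim(v)
  g <- phantomTBM:::coordGrids(d)
  moved <- array(phantomTBM:::cpp_sample_trilinear(
    as.double(v), as.integer(d), g$x + 3, g$y - 2, g$z + 1, 0), dim = d)
  tr <- registerAffine(moved, v, dof = 12)
  expect_lt(max(abs(tr$t - c(-3, 2, -1))), 0.5)
  sc <- scaledVolume(v, 1.05)
  tr9 <- registerAffine(sc, v, dof = 9)
  expect_lt(max(abs(diag(tr9$A) - 1.05)), 0.01)
})

test_that("registration is equivariant under a common integer translation", {
  tpl <- smallTemplate()
  s <- synthesizeSubjectVolume(tpl, subjectRecord(dose = 2, hcy = 11.7),
                               quietEffect(percentPerAllele = -6), seed = 6)
  cfg <- registrationConfig()
  f0 <- registerNonlinear(s$volume, tpl, cfg)
  off <- c(2L, 0L, 0L)
  shiftVol <- function(v) {
    out <- array(0, dim(v))
    out[(1 + off[1]):dim(v)[1], , ] <- v[1:(dim(v)[1] - off[1]), , ]
    out
  }
  f1 <- registerNonlinear(shiftVol(s$volume), shiftVol(intensityVolume(tpl)),
                          cfg)
  d <- dim(s$volume)
  inner0 <- displacement(f0)[5:(d[1] - 5), 5:(d[2] - 5), 5:(d[3] - 5), ]
  inner1 <- displacement(f1)[(5 + off[1]):(d[1] - 5 + off[1]),
                             5:(d[2] - 5), 5:(d[3] - 5), ]
  expect_lt(max(abs(inner1 - inner0)), 0.2)
})

test_that("MDT of identical inputs is the common volume with null fields", {
  tpl <- smallTemplate()
  v <- intensityVolume(tpl)
  m <- buildMDT(list(v, v, v), nIter = 1L)
  expect_equal(m$mdt, v, tolerance = 1e-12)
  for (f in m$fields) expect_lt(max(abs(displacement(f))), 1e-8)
})

test_that("MDT centers a group of globally scaled phantoms", {
  tpl <- midTemplate()
  v <- intensityVolume(tpl)
  set.seed(3)
  scales <- exp(runif(6, log(0.95), log(1.05)))
  vols <- lapply(scales, function(s) scaledVolume(v, s))
  m <- buildMDT(vols, nIter = 2L)
  mask <- labelVolume(tpl) > 0
  meanLogJ <- vapply(m$fields, function(f)
    mean(log(jacobian(jacobianDeterminant(f))[mask])), numeric(1))
  expect_lt(abs(mean(meanLogJ)), 0.01)
  # recovered per-subject log-volume changes track the true scalings
  expect_gt(cor(meanLogJ, log(scales^3)), 0.98)
})

test_that("MDT mean displacement does not grow with more iterations", {
  tpl <- smallTemplate()
  v <- intensityVolume(tpl)
  set.seed(9)
  vols <- lapply(exp(runif(4, log(0.96), log(1.04))),
                 function(s) scaledVolume(v, s))
  cfg <- registrationConfig(itersPerLevel = c(40L, 25L, 12L))
  m3 <- buildMDT(vols, nIter = 3L, cfg)
  expect_lte(m3$meanDisplacement[3], m3$meanDisplacement[2] + 0.005)
  expect_lte(m3$meanDisplacement[2], m3$meanDisplacement[1] + 0.005)
})
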