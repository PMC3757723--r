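#' Construct the deterministic nested-ellipsoid phantom template
#'
#' Builds a labeled 3D volume that stands in for a population average
#' (minimal deformation) brain template: a gray-matter shell (label 1)
#' around a periventricular white-matter compartment (label 2) around a
#' central ventricle (label 3), plus a brainstem ellipsoid (label 4)
#' protruding inferiorly, on a background of 0. The intensity volume is a
#' per-tissue base level plus a smooth deterministic sinusoidal texture so
#' that intensity gradients exist inside compartments, which is what
#' drives intensity-based registration there. No randomness is involved.
#'
#' @param gridShape three positive integers (>= 32 per axis).
#' @param geometry optional list overriding \code{\link{phantomGeometry}}:
#'   elements \code{radii} (outer brain semi-axes, voxels),
#'   \code{gmThickness} (gray-matter shell thickness, voxels),
#'   \code{ventricleFraction} (ventricle semi-axes as a fraction of the
#'   white-matter semi-axes), \code{stemRadii} and \code{stemOffset}
#'   (brainstem ellipsoid, voxels).
#' @param voxelSize isotropic voxel edge in mm.
#' @return a \linkS4class{PhantomTemplate}.
#' @examples
#' tpl <- makeTemplatePhantom(c(48, 48, 48))
#' table(labelVolume(tpl))
#' @export
makeTemplatePhantom <- function(gridShape, geometry = NULL, voxelSize = 1) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 32L))
    stop("gridShape must be three integers >= 32")
  geo <- phantomGeometry(gridShape)
  if (!is.null(geometry)) geo[names(geometry)] <- geometry
  center <- (gridShape - 1) / 2
  # geometry must leave a >= 2-voxel background margin on every axis
  for (ax in 1:3) {
    if (center[ax] - geo$radii[ax] < 2)
      stop("brain ellipsoid exceeds grid on axis ", ax,
           " (radius ", geo$radii[ax], ", half-extent ", center[ax], ")")
    stemHi <- geo$stemOffset[ax] + geo$stemRadii[ax]
    stemLo <- geo$stemOffset[ax] - geo$stemRadii[ax]
    if (center[ax] + stemHi > gridShape[ax] - 3 || center[ax] + stemLo < 2)
      stop("brainstem ellipsoid exceeds grid on axis ", ax)
  }
  wmRadii <- geo$radii - geo$gmThickness
  if (any(wmRadii <= 1))
    stop("gmThickness leaves no white-matter compartment")
  ventRadii <- wmRadii * geo$ventricleFraction

  geoFull <- c(geo, list(center = center, wmRadii = wmRadii,
                         ventRadii = ventRadii))
  g <- coordGrids(gridShape)
  labels <- array(phantomLabelsAt(geoFull, g$x, g$y, g$z), dim = gridShape)

  base <- c(0, 0.45, 0.75, 0.12, 0.6)[labels + 1L]
  texture <- 0.08 * sin(2 * pi * g$x / 9.5) *
    sin(2 * pi * g$y / 8.5) * sin(2 * pi * g$z / 10.5)
  intensity <- base + ifelse(labels > 0L, texture, 0)
  intensity <- array(pmin(pmax(intensity, 0), 1), dim = gridShape)

  new("PhantomTemplate", intensity = intensity, labels = labels,
      voxelSize = voxelSize, geometry = geoFull)
}

# Analytic label assignment at arbitrary (possibly fractional) 0-based
# coordinates: the phantom geometry is closed form, so the deformed label
# volume of a warped phantom can be evaluated exactly at warped points.
phantomLabelsAt <- function(geo, xs, ys, zs) {
  rho <- function(ctr, radii)
    sqrt(((xs - ctr[1]) / radii[1])^2 + ((ys - ctr[2]) / radii[2])^2 +
           ((zs - ctr[3]) / radii[3])^2)
  lab <- rep(0L, length(xs))
  lab[rho(geo$center, geo$radii) <= 1] <- 1L
  stem <- rho(geo$center + geo$stemOffset, geo$stemRadii) <= 1
  lab[stem & lab %in% c(0L, 1L)] <- 4L
  lab[rho(geo$center, geo$wmRadii) <= 1] <- 2L
  lab[rho(geo$center, geo$ventRadii) <= 1] <- 3L
  lab
}

#' Default phantom geometry for a grid
#'
#' Semi-axes scale with the grid so the brain fills most of the volume
#' with a comfortable background margin.
#'
#' @param gridShape three positive integers.
#' @return list of geometry parameters (see \code{\link{makeTemplatePhantom}}).
#' @export
phantomGeometry <- function(gridShape) {
  half <- (as.integer(gridShape) - 1) / 2
  radii <- round(half * c(0.81, 0.77, 0.72), 1)
  list(radii = radii,
       gmThickness = max(2, round(min(gridShape) / 10)),
       ventricleFraction = 0.35,
       stemRadii = round(pmax(2, half * c(0.17, 0.17, 0.24)), 1),
       stemOffset = c(0, 0, round(half[3] * 0.60, 1)))
}

#' Simulate Hardy-Weinberg genotype doses
#'
#' Draws risk-allele counts 0/1/2 with probabilities
#' \eqn{((1-q)^2, 2q(1-q), q^2)} for minor-allele frequency \eqn{q}.
#' The default frequency of 0.31 matches the reported MTHFR C677T minor
#' allele frequency in Western and Central Europeans.
#'
#' @param n number of subjects.
#' @param maf minor-allele frequency in \code{[0, 0.5]}.
#' @param seed RNG seed.
#' @return integer vector of doses.
#' @examples
#' table(simulateGenotypes(1000, maf = 0.31, seed = 1))
#' @export
simulateGenotypes <- function(n, maf = 0.31, seed = 1L) {
  if (maf < 0 || maf > 0.5) stop("maf must lie in [0, 0.5]")
  if (n < 1) stop("n must be >= 1")
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  withSeed(seed, sample(0:2, n, replace = TRUE, prob = p))
}

#' Default effect specification
#'
#' Defaults are calibrated to the reported study conditions: up to a 6
#' percent white-matter volume deficit per risk allele cross-sectionally,
#' a 1.5 percent-per-year progression per allele longitudinally, and a
#' homocysteine elevation of about 0.75 micromol/L per allele (group
#' means 10.2 at dose 0 rising to 11.7 at dose 2).
#'
#' @param percentPerAllele,targetLabel,annualPercentPerAllele,mediationFraction,hcyPerAllele,hcyBaseline,hcySD,nuisanceWarpMM,noiseSD see \linkS4class{EffectSpec}.
#' @return an \linkS4class{EffectSpec}.
#' @export
effectSpec <- function(percentPerAllele = -6, targetLabel = 2L,
                       annualPercentPerAllele = -1.5, mediationFraction = 0,
                       hcyPerAllele = 0.75, hcyBaseline = 10.2, hcySD = 2.4,
                       nuisanceWarpMM = 0.5, noiseSD = 0.02) {
  new("EffectSpec", percentPerAllele = percentPerAllele,
      targetLabel = as.integer(targetLabel),
      annualPercentPerAllele = annualPercentPerAllele,
      mediationFraction = mediationFraction, hcyPerAllele = hcyPerAllele,
      hcyBaseline = hcyBaseline, hcySD = hcySD,
      nuisanceWarpMM = nuisanceWarpMM, noiseSD = noiseSD)
}

#' Simulate subject covariates for given genotype doses
#'
#' Ages are Normal(75, 7) truncated to [55, 95] years; sex is Bernoulli
#' (1 = male, 0 = female); homocysteine is
#' \code{hcyBaseline + hcyPerAllele * dose} plus Normal(0, hcySD) noise;
#' folate is drawn independently of dose; ApoE4 allele counts are drawn
#' independently at a carrier frequency typical of elderly MCI cohorts.
#'
#' @param doses integer vector of allele doses.
#' @param effect an \linkS4class{EffectSpec} (homocysteine calibration).
#' @param ageMean,ageSD,maleFraction demographic settings.
#' @param seed RNG seed.
#' @param longitudinal if TRUE, draw follow-up intervals with
#'   \code{\link{sampleFollowupInterval}}.
#' @return data.frame with columns subject_id, dose, age, sex, hcy,
#'   folate, apoe4, interval_months (NA when cross-sectional).
#' @export
simulateCovariates <- function(doses, effect = effectSpec(), ageMean = 75,
                               ageSD = 7, maleFraction = 0.64, seed = 1L,
                               longitudinal = FALSE) {
  if (length(doses) == 0) stop("doses must be nonempty")
  n <- length(doses)
  withSeed(seed, {
    age <- rnorm(n, ageMean, ageSD)
    while (any(bad <- age < 55 | age > 95))
      age[bad] <- rnorm(sum(bad), ageMean, ageSD)
    sex <- rbinom(n, 1, maleFraction)
    hcy <- effect@hcyBaseline + effect@hcyPerAllele * doses +
      rnorm(n, 0, effect@hcySD)
    hcy <- pmax(hcy, 0.5)            # plasma level must stay positive
    folate <- pmax(rnorm(n, 500, 150), 50)
    apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.42, 0.13))
    interval <- rep(NA_real_, n)
    if (longitudinal)
      interval <- sampleFollowupInterval(n, seed = seed + 1L)
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               dose = as.integer(doses), age = age, sex = as.integer(sex),
               hcy = hcy, folate = folate, apoe4 = as.integer(apoe4),
               interval_months = interval, stringsAsFactors = FALSE)
  })
}

#' Sample follow-up scan intervals
#'
#' Uses the printed follow-up frequency table of the longitudinal cohort:
#' 1, 59, 176, 52, 12 and 7 subjects re-scanned at 10, 12, 13, 14, 15 and
#' 16 months respectively (n = 307).
#'
#' @param n number of intervals.
#' @param seed RNG seed.
#' @return numeric vector of months.
#' @export
sampleFollowupInterval <- function(n, seed = 1L) {
  months <- c(10, 12, 13, 14, 15, 16)
  freq <- c(1, 59, 176, 52, 12, 7)
  withSeed(seed, sample(months, n, replace = TRUE, prob = freq / sum(freq)))
}

# Radial warp profile, template -> subject, in normalized elliptical
# radius. Three zones along each ray:
#   core (rho <= rho1):        uniform scaling R = s*rho, Jacobian s^3;
#   tissue (rho1 < rho <= rho3): incompressible radial flow
#                              R = (rho^3 - delta)^(1/3) with
#                              delta = (1 - s^3) * rho1^3, Jacobian
#                              exactly 1 (tissue outside the target is
#                              rigidly displaced, not deformed);
#   blend (rho3 < rho < rho2): the residual displacement decays to zero
#                              through a C1 smoothstep; the compensating
#                              volume change lives here, and rho3 is
#                              chosen beyond the outer brain surface so
#                              this zone lies in background.
# The analytic Jacobian determinant is R'(rho) * (R(rho)/rho)^2.
radialProfile <- function(rho, s, rho1, rho3, rho2) {
  delta <- (1 - s^3) * rho1^3
  core <- rho <= rho1
  Rinc <- (pmax(rho^3 - delta, 1e-9))^(1 / 3)
  dRinc <- rho^2 / Rinc^2
  t <- pmin(pmax((rho - rho3) / (rho2 - rho3), 0), 1)
  h <- 1 - (3 * t^2 - 2 * t^3)
  dh <- ifelse(rho > rho3 & rho < rho2, -(6 * t - 6 * t^2) / (rho2 - rho3), 0)
  disp <- Rinc - rho
  R <- ifelse(core, s * rho, rho + h * disp)
  dR <- ifelse(core, s, 1 + dh * disp + h * (dRinc - 1))
  ratio <- ifelse(rho > 0, R / rho, s)
  list(R = R, dR = dR, jac = dR * ratio^2)
}

# Invert the radial profile by vectorized Newton iteration.
radialProfileInverse <- function(target, s, rho1, rho3, rho2) {
  rho <- ifelse(target <= s * rho1, target / s, target)
  for (it in 1:12) {
    p <- radialProfile(rho, s, rho1, rho3, rho2)
    rho <- pmax(rho - (p$R - target) / pmax(p$dR, 1e-6), 0)
  }
  rho
}

# Core contraction factor implied by a subject's dose and homocysteine.
impliedCoreJacobian <- function(record, effect, extraPercent = 0) {
  direct <- effect@percentPerAllele * record$dose * (1 - effect@mediationFraction)
  mediated <- if (effect@mediationFraction > 0)
    effect@percentPerAllele * effect@mediationFraction *
      (record$hcy - effect@hcyBaseline) / effect@hcyPerAllele
  else 0
  pct <- direct + mediated
  j <- (1 + pct / 100) * (1 + extraPercent / 100)
  if (j <= 0)
    stop("requested contraction of ", signif((j - 1) * 100, 4),
         "% is <= -100%: non-invertible warp")
  j
}

# Shared machinery of the cross-sectional and longitudinal synthesizers.
synthesizeCore <- function(template, record, effect, seed, extraPercent = 0,
                           noiseSalt = 0L) {
  if (!(effect@targetLabel %in% template@labels))
    stop("target label ", effect@targetLabel, " not present in template")
  d <- gridShape(template)
  geo <- template@geometry
  center <- geo$center
  wmRadii <- geo$wmRadii
  j <- impliedCoreJacobian(record, effect, extraPercent)
  s <- j^(1 / 3)
  rho1 <- 1.02
  # incompressible zone must cover the whole brain surface; the blend
  # (where the compensating volume change lives) then sits in background
  # and must end strictly inside the grid along every axis
  rho3 <- max(geo$radii / wmRadii) + 0.03
  rho2 <- 0.97 * min(center / wmRadii, (d - 1 - center) / wmRadii)
  if (rho2 <= rho3 + 0.05)
    stop("no room for the warp's background blend annulus")
  probe <- radialProfile(seq(0, rho2, length.out = 600), s, rho1, rho3, rho2)
  if (min(probe$dR) <= 0)
    stop("implanted warp is non-monotone (contraction too extreme)")

  g <- coordGrids(d)
  zx <- (g$x - center[1]) / wmRadii[1]
  zy <- (g$y - center[2]) / wmRadii[2]
  zz <- (g$z - center[3]) / wmRadii[3]
  rhoY <- sqrt(zx^2 + zy^2 + zz^2)
  rhoX <- radialProfileInverse(rhoY, s, rho1, rho3, rho2)
  scale <- ifelse(rhoY > 0, rhoX / rhoY, 1 / s)
  sx <- center[1] + (g$x - center[1]) * scale
  sy <- center[2] + (g$y - center[2]) * scale
  sz <- center[3] + (g$z - center[3]) * scale

  vol <- array(cpp_sample_trilinear(as.double(template@intensity),
                                    as.integer(d), sx, sy, sz, 0),
               dim = d)
  # deformed labels evaluated analytically at the warped sample points
  warpedLabels <- array(phantomLabelsAt(geo, sx, sy, sz), dim = d)

  gt <- radialProfile(rhoY, s, rho1, rho3, rho2)$jac
  gtJac <- new("JacobianMap", j = array(gt, dim = d),
               voxelSize = template@voxelSize, clampedCount = 0L)

  # nuisance warp: same per-subject field at both timepoints
  if (effect@nuisanceWarpMM > 0) {
    nseed <- subjectSeed(seed, record$subject_id, salt = 101L)
    u <- withSeed(nseed, {
      amp <- effect@nuisanceWarpMM / template@voxelSize
      comp <- lapply(1:3, function(i) {
        f <- smooth3D(array(rnorm(prod(d)), dim = d), 4)
        f <- f / sd(f) * amp
        array(cpp_zero_shell(as.double(f), as.integer(d)), dim = d)
      })
      array(c(comp[[1]], comp[[2]], comp[[3]]), dim = c(d, 3))
    })
    vol <- array(cpp_warp_field(as.double(vol), as.integer(d),
                                as.double(u[, , , 1]), as.double(u[, , , 2]),
                                as.double(u[, , , 3]), 0), dim = d)
  }
  if (effect@noiseSD > 0) {
    nseed <- subjectSeed(seed, record$subject_id, salt = 202L + noiseSalt)
    vol <- vol + withSeed(nseed, array(rnorm(prod(d), 0, effect@noiseSD), dim = d))
  }
  list(volume = vol, groundTruthJacobian = gtJac, warpedLabels = warpedLabels,
       coreJacobian = j)
}

#' Synthesize one subject volume with an implanted dose effect
#'
#' Applies, in order: (i) an analytic dose-scaled radial contraction
#' centered on the white-matter compartment whose Jacobian determinant
#' inside the target region equals
#' \code{1 + (percentPerAllele * dose * (1 - mediationFraction) + mediated
#' component) / 100}, where the mediated component is driven by the
#' subject's homocysteine deviation from baseline; (ii) a random smooth
#' nuisance warp; (iii) additive Gaussian intensity noise. The analytic
#' per-voxel Jacobian of the implanted warp is returned alongside the
#' volume, as is the deformed label volume.
#'
#' @param template a \linkS4class{PhantomTemplate}.
#' @param record one-row data.frame as from \code{\link{simulateCovariates}}.
#' @param effect an \linkS4class{EffectSpec}.
#' @param seed run-level seed; per-subject streams are derived by stable
#'   hashing of the subject id.
#' @return list with elements \code{volume} (3D array),
#'   \code{groundTruthJacobian} (\linkS4class{JacobianMap}),
#'   \code{warpedLabels} (3D integer array) and \code{coreJacobian}
#'   (scalar implanted determinant in the target region).
#' @export
synthesizeSubjectVolume <- function(template, record, effect = effectSpec(),
                                    seed = 1L) {
  synthesizeCore(template, record, effect, seed)
}

#' Synthesize a baseline / follow-up volume pair
#'
#' The follow-up volume adds an extra contraction of
#' \code{annualPercentPerAllele * dose * interval_months / 12} percent in
#' the target region on top of the baseline warp. The nuisance warp is
#' shared between the two timepoints (same anatomy), while the intensity
#' noise is drawn independently. If the record carries no interval, one is
#' drawn from the printed follow-up frequency table.
#'
#' @inheritParams synthesizeSubjectVolume
#' @return list with elements \code{baseline} and \code{followup} (each as
#'   returned by \code{\link{synthesizeSubjectVolume}}) plus
#'   \code{intervalMonths}.
#' @export
synthesizeFollowupPair <- function(template, record, effect = effectSpec(),
                                   seed = 1L) {
  interval <- record$interval_months
  if (is.null(interval) || is.na(interval))
    interval <- sampleFollowupInterval(1, seed = subjectSeed(seed, record$subject_id, 7L))
  if (interval < 6 || interval > 24)
    stop("interval_months must lie in [6, 24]")
  extra <- effect@annualPercentPerAllele * record$dose * interval / 12
  base <- synthesizeCore(template, record, effect, seed, extraPercent = 0,
                         noiseSalt = 0L)
  fu <- synthesizeCore(template, record, effect, seed, extraPercent = extra,
                       noiseSalt = 1L)
  list(baseline = base, followup = fu, intervalMonths = interval)
}
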