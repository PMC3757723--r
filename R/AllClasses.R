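#' Labeled 3D phantom template
#'
#' A deterministic nested-ellipsoid volume standing in for a population
#' brain template: a scalar intensity grid in \code{[0, 1]} plus an integer
#' label grid with codes background = 0, gray-matter shell = 1,
#' periventricular white matter = 2, ventricle = 3, brainstem = 4.
#' Voxel indices are 0-based and axis-aligned (identity orientation).
#'
#' @slot intensity 3D numeric array in \code{[0, 1]}.
#' @slot labels 3D integer array of tissue codes (same grid).
#' @slot voxelSize positive scalar, isotropic voxel edge in mm.
#' @slot geometry list of the ellipsoid parameters the template was built
#'   from (center, outer/white-matter/ventricle radii, brainstem).
#' @export
setClass("PhantomTemplate",
  representation(intensity = "array", labels = "array",
                 voxelSize = "numeric", geometry = "list"))

setValidity("PhantomTemplate", function(object) {
  msgs <- character()
  if (!identical(dim(object@intensity), dim(object@labels)))
    msgs <- c(msgs, "intensity and labels must share grid_shape")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msgs <- c(msgs, "voxelSize must be a positive scalar")
  lab <- object@labels
  if (!all(lab %in% 0:4))
    msgs <- c(msgs, "labels must be in 0..4")
  if (sum(lab == 2L) == 0L)
    msgs <- c(msgs, "white-matter region (label 2) is empty")
  # label-2 must be interior: no face-adjacency with background
  if (sum(lab == 2L) > 0L) {
    touching <- dilate6(lab == 0L) & (lab == 2L)
    if (any(touching))
      msgs <- c(msgs, "label-2 region touches background")
  }
  if (length(msgs)) msgs else TRUE
})

#' Implanted effect specification for the phantom simulator
#'
#' Describes the ground-truth signal implanted in synthetic subjects: a
#' per-allele percent volume change in a target tissue label, an optional
#' annualized progression rate for longitudinal pairs, and a homocysteine
#' mediation pathway routing part of the dose effect through plasma
#' homocysteine.
#'
#' @slot percentPerAllele percent volume change per risk allele in the
#'   target label (negative = deficit).
#' @slot targetLabel integer tissue code carrying the effect.
#' @slot annualPercentPerAllele percent per year per allele (longitudinal).
#' @slot mediationFraction share in \code{[0, 1]} of the dose effect routed
#'   through homocysteine.
#' @slot hcyPerAllele homocysteine increment per allele (micromol/L).
#' @slot hcyBaseline mean homocysteine at dose 0 (micromol/L).
#' @slot hcySD residual homocysteine SD within genotype (micromol/L).
#' @slot nuisanceWarpMM amplitude of random smooth nuisance warps (mm,
#'   per-component RMS).
#' @slot noiseSD additive Gaussian intensity noise SD (intensity units).
#' @export
setClass("EffectSpec",
  representation(percentPerAllele = "numeric", targetLabel = "integer",
                 annualPercentPerAllele = "numeric",
                 mediationFraction = "numeric", hcyPerAllele = "numeric",
                 hcyBaseline = "numeric", hcySD = "numeric",
                 nuisanceWarpMM = "numeric", noiseSD = "numeric"))

setValidity("EffectSpec", function(object) {
  msgs <- character()
  if (object@mediationFraction < 0 || object@mediationFraction > 1)
    msgs <- c(msgs, "mediationFraction must lie in [0, 1]")
  if (!(object@targetLabel %in% 1:4))
    msgs <- c(msgs, "targetLabel must be a tissue code in 1..4")
  if (object@mediationFraction > 0 && object@hcyPerAllele <= 0)
    msgs <- c(msgs, "mediation requires a positive hcyPerAllele")
  if (object@hcySD < 0 || object@noiseSD < 0 || object@nuisanceWarpMM < 0)
    msgs <- c(msgs, "dispersion parameters must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Nonlinear registration settings
#'
#' Controls the diffusion-regularized demons registration: multiresolution
#' depth, iteration caps, Gaussian regularization widths for the update and
#' the accumulated field, a per-iteration displacement cap, an optional
#' symmetric (inverse-consistent) mode, and the relative
#' similarity-improvement stopping tolerance.
#'
#' @slot nLevels pyramid depth (>= 1); each level halves resolution.
#' @slot itersPerLevel integer iteration caps, coarse to fine (recycled).
#' @slot updateSigma Gaussian width (voxels) smoothing each update.
#' @slot fieldSigma Gaussian width (voxels) smoothing the accumulated field.
#' @slot stepCap maximum per-iteration displacement (voxels).
#' @slot symmetric estimate forward and backward fields jointly and average
#'   them antisymmetrically (inverse-consistent mode).
#' @slot tol relative SSD-improvement stopping threshold.
#' @export
setClass("RegistrationConfig",
  representation(nLevels = "integer", itersPerLevel = "integer",
                 updateSigma = "numeric", fieldSigma = "numeric",
                 stepCap = "numeric", symmetric = "logical", tol = "numeric"))

setValidity("RegistrationConfig", function(object) {
  msgs <- character()
  if (object@nLevels < 1L) msgs <- c(msgs, "nLevels must be >= 1")
  if (any(object@itersPerLevel < 1L)) msgs <- c(msgs, "itersPerLevel must be >= 1")
  if (object@updateSigma < 0 || object@fieldSigma < 0)
    msgs <- c(msgs, "sigmas must be >= 0")
  if (object@stepCap <= 0) msgs <- c(msgs, "stepCap must be > 0")
  if (object@tol < 0) msgs <- c(msgs, "tol must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Dense displacement field
#'
#' Per-voxel 3-vector displacement on the fixed-image grid, in voxel
#' units. The transform maps fixed-grid coordinate \code{x} to
#' moving-image coordinate \code{x + u(x)}; its Jacobian determinant
#' \code{det(I + grad u)} is the local volume expansion factor of the
#' fixed-to-moving deformation.
#'
#' @slot u 4D numeric array \code{c(gridShape, 3)}, voxel units.
#' @slot voxelSize isotropic voxel edge in mm (reporting only; all
#'   internal math is in voxel units).
#' @export
setClass("DisplacementField",
  representation(u = "array", voxelSize = "numeric"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@u)
  if (length(d) != 4L || d[4] != 3L)
    return("u must be a 4D array with last dimension 3")
  if (!all(is.finite(object@u)))
    return("displacement field contains non-finite values")
  TRUE
})

#' Jacobian determinant map
#'
#' Per-voxel volume expansion factor of a deformation relative to the
#' template (1 = no change, < 1 contraction, > 1 expansion).
#'
#' @slot j 3D numeric array of determinants.
#' @slot voxelSize voxel edge in mm.
#' @slot clampedCount number of voxels clamped at the positivity floor.
#' @export
setClass("JacobianMap",
  representation(j = "array", voxelSize = "numeric", clampedCount = "integer"))

setValidity("JacobianMap", function(object) {
  if (any(object@j <= 0)) return("Jacobian map must be strictly positive")
  TRUE
})

#' Percent volume-change map
#'
#' Per-voxel percent volume difference relative to the template
#' (cross-sectional mode) or percent change per year (annualized mode).
#' This is the dependent variable of the voxel-wise association model.
#'
#' @slot values 3D numeric array, percent.
#' @slot mode \code{"cross_sectional"} or \code{"annualized"}.
#' @slot voxelSize voxel edge in mm.
#' @export
setClass("ChangeMap",
  representation(values = "array", mode = "character", voxelSize = "numeric"))

setValidity("ChangeMap", function(object) {
  if (!object@mode %in% c("cross_sectional", "annualized"))
    return("mode must be 'cross_sectional' or 'annualized'")
  if (any(object@values <= -100))
    return("percent change must be > -100 everywhere")
  TRUE
})

#' Voxel-wise regression design matrix
#'
#' Subjects-by-predictors design for the additive allele-dose model, with
#' an intercept, the raw 0/1/2 dose, mean-centered age, sex, and any
#' requested adjustment covariates. Complete-case: subjects missing a
#' required covariate are dropped and recorded.
#'
#' @slot X numeric matrix with named columns; first columns are
#'   (intercept, dose, age, sex).
#' @slot subjectIds character ids aligned with rows of X.
#' @slot droppedIds ids excluded by the complete-case rule.
#' @slot model adjustment-set name the design was built for.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", subjectIds = "character",
                 droppedIds = "character", model = "character"))

setValidity("DesignMatrix", function(object) {
  X <- object@X
  msgs <- character()
  if (nrow(X) != length(object@subjectIds))
    msgs <- c(msgs, "subjectIds must align with rows of X")
  if (qr(X)$rank < ncol(X))
    msgs <- c(msgs, "design matrix is rank deficient")
  if (nrow(X) <= ncol(X) + 5L)
    msgs <- c(msgs, "need n_subjects > k + 5")
  if (!"dose" %in% colnames(X) || var(X[, "dose"]) == 0)
    msgs <- c(msgs, "dose column missing or has zero variance")
  if (length(msgs)) msgs else TRUE
})

#' Voxel-wise statistical maps
#'
#' Per-predictor beta (percent per unit), standard-error, t and two-sided
#' p maps from the mass-univariate fit, plus the residual variance map,
#' the analysis mask, and the valid-voxel mask (masked voxels whose
#' response had nonzero variance across subjects).
#'
#' @slot predictors character vector of predictor names.
#' @slot beta,se,tstat,pval named lists of 3D arrays (NA outside mask).
#' @slot sigma2 3D array of residual variance estimates.
#' @slot df residual degrees of freedom (n - k).
#' @slot n number of subjects fitted.
#' @slot mask logical 3D analysis mask.
#' @slot valid logical 3D mask of valid (non-degenerate) voxel tests.
#' @export
setClass("StatMapSet",
  representation(predictors = "character", beta = "list", se = "list",
                 tstat = "list", pval = "list", sigma2 = "array",
                 df = "numeric", n = "integer", mask = "array",
                 valid = "array"))

#' Benjamini-Hochberg FDR result
#'
#' The step-up critical p-value at level q over m valid tests: the highest
#' p-value threshold at which the expected proportion of false positives
#' among surviving tests is q. \code{criticalP} is 0 exactly when nothing
#' survives.
#'
#' @slot q target FDR level.
#' @slot m number of valid tests.
#' @slot criticalP highest surviving p-value threshold (0 if none).
#' @slot nSurviving number of tests with p <= criticalP.
#' @slot survivors logical vector aligned with the input p-values.
#' @export
setClass("FDRResult",
  representation(q = "numeric", m = "integer", criticalP = "numeric",
                 nSurviving = "integer", survivors = "logical"))

setValidity("FDRResult", function(object) {
  msgs <- character()
  if (object@criticalP < 0 || object@criticalP > 1)
    msgs <- c(msgs, "criticalP must lie in [0, 1]")
  if ((object@nSurviving == 0L) != (object@criticalP == 0))
    msgs <- c(msgs, "nSurviving must be 0 exactly when criticalP is 0")
  if (length(msgs)) msgs else TRUE
})
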