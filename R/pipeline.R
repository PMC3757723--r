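#' Assemble a full pipeline run configuration
#'
#' Defaults reflect the study conditions the simulator emulates: minor
#' allele frequency 0.31, ages 75 +/- 7 years, homocysteine rising about
#' 0.75 micromol/L per risk allele from a baseline of 10.2, a -6 percent
#' per-allele white-matter deficit cross-sectionally and -1.5 percent per
#' year per allele longitudinally, with the cohort scaled to a
#' desk-size n of 120.
#'
#' @param seed run seed; every random draw derives from it.
#' @param n cohort size.
#' @param maf minor-allele frequency.
#' @param gridShape phantom grid.
#' @param effect an \linkS4class{EffectSpec}.
#' @param registration a \linkS4class{RegistrationConfig}.
#' @param smoothingSigma Gaussian width (voxels) applied to change maps
#'   before statistics.
#' @param models adjustment sets to fit (see \code{\link{assembleDesign}}).
#' @param q FDR level.
#' @param mode \code{"cross_sectional"} or \code{"longitudinal"}.
#' @param mdtSubjects number of volumes used to build a minimal
#'   deformation template before registration (0 = register directly to
#'   the phantom template).
#' @param mdtIter MDT refinement iterations.
#' @param outDir output directory (NULL = no files written).
#' @param ageMean,ageSD,maleFraction demographics.
#' @return a run-configuration list.
#' @export
runConfig <- function(seed = 1L, n = 120L, maf = 0.31,
                      gridShape = c(48L, 48L, 48L), effect = effectSpec(),
                      registration = registrationConfig(),
                      smoothingSigma = 1.5, models = c("base"),
                      q = 0.05, mode = "cross_sectional", mdtSubjects = 0L,
                      mdtIter = 2L, outDir = NULL, ageMean = 75, ageSD = 7,
                      maleFraction = 0.64) {
  mode <- match.arg(mode, c("cross_sectional", "longitudinal"))
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  structure(list(seed = as.integer(seed), n = as.integer(n), maf = maf,
                 gridShape = as.integer(gridShape), effect = effect,
                 registration = registration,
                 smoothingSigma = smoothingSigma, models = models, q = q,
                 mode = mode, mdtSubjects = as.integer(mdtSubjects),
                 mdtIter = as.integer(mdtIter), outDir = outDir,
                 ageMean = ageMean, ageSD = ageSD,
                 maleFraction = maleFraction),
            class = "tbmRunConfig")
}

configAsList <- function(config) {
  eff <- config$effect
  reg <- config$registration
  c(config[setdiff(names(config), c("effect", "registration"))],
    list(effect = lapply(slotNames(eff), function(s) slot(eff, s)),
         registration = lapply(slotNames(reg), function(s) slot(reg, s))))
}

#' Run the full phantom TBM association pipeline
#'
#' Executes simulate, optional MDT construction, registration, Jacobian
#' and percent-change mapping, smoothing, the voxel-wise dose regressions
#' for every requested adjustment model, FDR thresholding, and the
#' summary report; all draws derive from the configured seed, so two runs
#' with the same configuration give identical summaries. In longitudinal
#' mode each subject's follow-up scan is registered to their baseline and
#' the change map is annualized by that subject's actual interval.
#'
#' @param config a configuration from \code{\link{runConfig}}.
#' @param keepMaps also return the per-model \linkS4class{StatMapSet}s
#'   and the subject change-map stack (memory permitting).
#' @return a run manifest: list with \code{summary} (per-model
#'   data.frame), \code{covariates}, \code{attenuation} (when both base
#'   and +hcy models ran), \code{wmRegression}, \code{configHash},
#'   \code{files}, \code{timings}, \code{warnings}, and when
#'   \code{keepMaps} the fitted maps.
#' @export
runPipeline <- function(config, keepMaps = FALSE) {
  stopifnot(inherits(config, "tbmRunConfig"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  files <- character(0)
  warnings <- character(0)
  logw <- function(...) warnings <<- c(warnings, paste0(...))
  tick <- function(stage) {
    timings[stage] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }
  out <- config$outDir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  # --- simulate ---------------------------------------------------------
  template <- makeTemplatePhantom(config$gridShape)
  doses <- simulateGenotypes(config$n, config$maf, seed = config$seed)
  covariates <- simulateCovariates(doses, config$effect,
                                   ageMean = config$ageMean,
                                   ageSD = config$ageSD,
                                   maleFraction = config$maleFraction,
                                   seed = config$seed + 1L,
                                   longitudinal = config$mode == "longitudinal")
  longitudinal <- config$mode == "longitudinal"
  subjects <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    rec <- covariates[i, ]
    subjects[[i]] <- if (longitudinal)
      synthesizeFollowupPair(template, rec, config$effect, config$seed)
    else synthesizeSubjectVolume(template, rec, config$effect, config$seed)
  }
  tick("simulate")

  # --- reference / MDT --------------------------------------------------
  reference <- intensityVolume(template)
  if (config$mdtSubjects >= 3L) {
    vols <- lapply(subjects[seq_len(min(config$mdtSubjects, config$n))],
                   function(s) if (longitudinal) s$baseline$volume else s$volume)
    mdt <- buildMDT(vols, nIter = config$mdtIter, config$registration,
                    voxelSize = voxelSize(template))
    reference <- mdt$mdt
  }
  tick("mdt")

  # --- register + change maps ------------------------------------------
  changeMaps <- vector("list", config$n)
  warpedLabels <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    s <- subjects[[i]]
    if (longitudinal) {
      field <- registerNonlinear(s$followup$volume, s$baseline$volume,
                                 config$registration,
                                 voxelSize = voxelSize(template))
      jm <- jacobianDeterminant(field)
      cm <- annualize(percentVolumeMap(jm), s$intervalMonths)
      warpedLabels[[i]] <- s$baseline$warpedLabels
    } else {
      field <- registerNonlinear(s$volume, reference, config$registration,
                                 voxelSize = voxelSize(template))
      jm <- jacobianDeterminant(field)
      cm <- percentVolumeMap(jm)
      warpedLabels[[i]] <- s$warpedLabels
    }
    if (jm@clampedCount > 0)
      logw("subject ", covariates$subject_id[i], ": ", jm@clampedCount,
           " clamped Jacobian voxels")
    changeMaps[[i]] <- smoothChangeMap(cm, config$smoothingSigma)
  }
  tick("register")

  # --- voxel-wise models ------------------------------------------------
  mask <- analysisMask(template)
  region <- labelVolume(template) == config$effect@targetLabel
  Y <- stackMaps(changeMaps, mask)
  fits <- list()
  summaries <- list()
  for (model in config$models) {
    design <- withCallingHandlers(
      assembleDesign(covariates, model),
      message = function(m) {
        logw(sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    keep <- match(design@subjectIds, covariates$subject_id)
    fit <- fitVoxelwise(Y[keep, , drop = FALSE], design, mask)
    fdr <- bhCriticalP(statMap(fit, "dose", "p")[fit@valid], q = config$q)
    thr <- thresholdMaps(fit, "dose", fdr)
    doseBeta <- statMap(fit, "dose", "beta")
    inRegion <- region & fit@valid
    summaries[[model]] <- data.frame(
      model = model, n = fit@n, df = fit@df,
      critical_p = thr$criticalP, n_surviving = thr$nSurviving,
      peak_abs_beta = thr$peakBeta,
      mean_dose_beta_region = mean(doseBeta[inRegion]),
      stringsAsFactors = FALSE)
    fits[[model]] <- fit
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  attenuation <- NULL
  if (all(c("base", "+hcy") %in% config$models))
    attenuation <- attenuationReport(fits[["base"]], fits[["+hcy"]], region)
  tick("glm")

  # --- scalar-level statistics -----------------------------------------
  wm <- labelVolumesCC(warpedLabels, voxelSize(template),
                       config$effect@targetLabel)
  wmReg <- wmVolumeRegression(covariates, wm)
  demo <- demographicsTable(covariates)
  tick("cohort")

  manifest <- list(summary = summary, covariates = covariates,
                   attenuation = attenuation, wmRegression = wmReg,
                   demographics = demo,
                   configHash = configHash(configAsList(config)),
                   timings = as.list(timings), warnings = warnings)
  if (keepMaps) {
    manifest$fits <- fits
    manifest$changeMaps <- changeMaps
    manifest$template <- template
    manifest$mask <- mask
    manifest$region <- region
  }

  # --- outputs ----------------------------------------------------------
  if (!is.null(out)) {
    covPath <- file.path(out, "covariates.tsv")
    writeCovariates(covariates, covPath)
    tplPath <- file.path(out, "template.nii.gz")
    writeVolume(template, tplPath)
    betaPath <- file.path(out, "dose_beta_base.nii.gz")
    betaArr <- statMap(fits[[config$models[1]]], "dose", "beta")
    betaArr[is.na(betaArr)] <- 0
    writeVolume(betaArr, betaPath, voxelSize(template),
                sidecar = list(mode = config$mode,
                               smoothing_sigma = config$smoothingSigma,
                               model = config$models[1],
                               config_hash = manifest$configHash))
    repPath <- file.path(out, "report.tsv")
    write.table(summary, repPath, sep = "\t", row.names = FALSE,
                quote = FALSE)
    files <- c(covPath, tplPath, betaPath, paste0(betaPath, ".json"),
               repPath)
    manifest$files <- files
    jsonlite::write_json(
      manifest[c("configHash", "files", "timings", "warnings")],
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    manifest$files <- c(files, file.path(out, "manifest.json"))
  } else manifest$files <- character(0)
  manifest
}
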