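# Scalar-level cohort statistics: genotype tables, group comparisons and
# the post-hoc white-matter volume regressions.

roundHalfAway <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Genotype percentage summary
#'
#' Percent homozygous (TT) and heterozygous (CT) risk-allele carriers,
#' rounded half-away-from-zero to one decimal.
#'
#' @param nCC,nCT,nTT genotype group counts.
#' @return named numeric vector \code{c(percent_tt, percent_ct)}.
#' @examples
#' genotypePercentages(149, 157, 53)   # the 359-subject cohort: 14.8, 43.7
#' @export
genotypePercentages <- function(nCC, nCT, nTT) {
  total <- nCC + nCT + nTT
  if (total <= 0) stop("total count must be positive")
  c(percent_tt = roundHalfAway(100 * nTT / total),
    percent_ct = roundHalfAway(100 * nCT / total))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson statistic with expectations from the product of margins, no
#' continuity correction; df = (r-1)(c-1).
#'
#' @param table r x c matrix of non-negative counts.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
contingencyChi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("every row and column margin must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' One-way fixed-effects ANOVA across genotype groups
#'
#' @param values numeric vector of a clinical measure.
#' @param groups group labels aligned with values.
#' @return list with \code{F}, \code{dfBetween}, \code{dfWithin}, \code{p}.
#' @export
groupAnova <- function(values, groups) {
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], dfBetween = tab[1, "Df"],
       dfWithin = tab[2, "Df"], p = tab[1, "Pr(>F)"])
}

#' Post-hoc white-matter volume regression
#'
#' Regresses per-hemisphere cerebral white-matter volumes (cc) on allele
#' dose adjusting for age and sex, reporting the dose coefficient and its
#' two-sided p per hemisphere.
#'
#' @param records data.frame with columns dose, age, sex (rows aligned
#'   with the volume table).
#' @param wmVolumes data.frame or matrix with columns \code{left} and
#'   \code{right} in cc.
#' @return list with per-hemisphere \code{beta} and \code{p}.
#' @export
wmVolumeRegression <- function(records, wmVolumes) {
  wmVolumes <- as.data.frame(wmVolumes)
  if (nrow(wmVolumes) != nrow(records))
    stop("wmVolumes rows do not align with records")
  if (nrow(records) <= 10L) stop("need n > 10")
  fitOne <- function(vol) {
    fit <- lm(vol ~ dose + age + sex, data = cbind(records, vol = vol))
    cf <- summary(fit)$coefficients["dose", ]
    list(beta = unname(cf["Estimate"]), p = unname(cf["Pr(>|t|)"]))
  }
  list(left = fitOne(wmVolumes$left), right = fitOne(wmVolumes$right))
}

#' White-matter volumes of synthesized subjects
#'
#' Volume (cc) of the target label in each subject's deformed label
#' volume: warped label-2 voxel count times voxel volume, split into left
#' and right hemispheres at the template midline. These stand in for
#' segmentation-derived volumes; the provenance is synthetic.
#'
#' @param warpedLabels list of 3D integer arrays (one per subject).
#' @param voxelSize voxel edge in mm.
#' @param label tissue code to measure (default 2, white matter).
#' @return data.frame with columns \code{left}, \code{right} in cc.
#' @export
labelVolumesCC <- function(warpedLabels, voxelSize = 1, label = 2L) {
  d <- dim(warpedLabels[[1]])
  mid <- d[1] / 2
  leftIdx <- seq_len(floor(mid))
  vox_cc <- voxelSize^3 / 1000
  res <- t(vapply(warpedLabels, function(w) {
    m <- w == label
    c(left = sum(m[leftIdx, , ]) * vox_cc,
      right = sum(m[-leftIdx, , ]) * vox_cc)
  }, numeric(2)))
  as.data.frame(res)
}

#' Genotype-split demographics table
#'
#' Per-genotype n, sex counts, and mean (SE) for each continuous measure,
#' with a chi-square test for sex and one-way ANOVA per continuous row.
#' SE is SD/sqrt(n). Empty genotype groups leave empty cells; tests then
#' degrade to the available groups with a warning.
#'
#' @param records data.frame of subject covariates.
#' @param measures named list of extra numeric vectors aligned with
#'   records (age, hcy, folate are always included when present).
#' @return list with \code{table} (data.frame, one row per measure) and
#'   \code{sexTest} (chi-square result or NULL).
#' @export
demographicsTable <- function(records, measures = list()) {
  if (nrow(records) == 0L) stop("records must be nonempty")
  doses <- factor(records$dose, levels = 0:2,
                  labels = c("CC", "CT", "TT"))
  present <- levels(doses)[table(doses) > 0]
  if (length(present) < 2L)
    warning("fewer than 2 genotype groups present; no tests emitted")
  base <- list(age = records$age)
  for (nm in c("hcy", "folate"))
    if (nm %in% names(records)) base[[nm]] <- records[[nm]]
  all <- c(base, measures)
  rows <- lapply(names(all), function(nm) {
    v <- all[[nm]]
    cells <- lapply(levels(doses), function(g) {
      x <- v[doses == g & !is.na(v)]
      if (length(x) == 0L) return(c(n = 0, mean = NA, se = NA))
      c(n = length(x), mean = mean(x), se = sd(x) / sqrt(length(x)))
    })
    usable <- doses[!is.na(v)]
    test <- if (length(present) >= 2L &&
                all(table(factor(usable, levels = present)) >= 2L)) {
      groupAnova(v[!is.na(v)], usable)
    } else NULL
    data.frame(measure = nm,
               n_cc = cells[[1]]["n"], mean_cc = cells[[1]]["mean"], se_cc = cells[[1]]["se"],
               n_ct = cells[[2]]["n"], mean_ct = cells[[2]]["mean"], se_ct = cells[[2]]["se"],
               n_tt = cells[[3]]["n"], mean_tt = cells[[3]]["mean"], se_tt = cells[[3]]["se"],
               F = if (is.null(test)) NA else test$F,
               p = if (is.null(test)) NA else test$p,
               row.names = NULL)
  })
  sexTest <- NULL
  if (length(present) >= 2L && "sex" %in% names(records)) {
    tab <- table(doses[doses %in% present], records$sex[doses %in% present])
    if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      sexTest <- contingencyChi2(tab)
  }
  list(table = do.call(rbind, rows), sexTest = sexTest,
       groupN = as.vector(table(doses)))
}
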