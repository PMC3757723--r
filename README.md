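# phantomTBM

Tensor-based morphometry (TBM) for imaging genetics, exercised end to end
on synthetic brain phantoms with exact ground truth.

TBM quantifies local brain volume differences by nonlinearly registering
each subject's scan to a population template and mapping the Jacobian
determinant of the deformation: J < 1 marks local tissue deficit, J > 1
expansion. In an imaging-genetics design the per-voxel percent volume
change becomes the response of a mass-univariate additive genetic model —
here the MTHFR C677T risk-allele dose in elderly subjects with mild
cognitive impairment:

    y = β0 + β_dose·dose + β_age·Age + β_sex·Sex + ε,   dose ∈ {0, 1, 2}

with optional adjustment for homocysteine, folate and ApoE4, and
Benjamini–Hochberg FDR control across voxels (critical p-value reported).

Because the MRI cohorts behind such analyses are access-controlled, the
package ships a phantom cohort generator whose implanted effects are known
in closed form: Hardy–Weinberg genotypes (MAF 0.31 by default),
calibrated dose-dependent homocysteine elevation (10.2 → 11.7 μmol/L
across CC → TT), an analytic periventricular white-matter contraction of
up to 6 %/allele (cross-sectional) or 1.5 %/yr/allele (longitudinal), a
tunable homocysteine mediation pathway, plus nuisance warps and image
noise. The pipeline is validated by recovering what was implanted.

The package provides, as S4 classes and camelCase functions:

* `makeTemplatePhantom()`, `simulateGenotypes()`, `simulateCovariates()`,
  `synthesizeSubjectVolume()`, `synthesizeFollowupPair()` — the generator;
* `registerAffine()`, `registerNonlinear()` (diffusion-regularized demons,
  optional symmetric inverse-consistent mode), `buildMDT()`,
  `warpVolume()`, `invertField()`, `inverseConsistencyError()`;
* `jacobianDeterminant()`, `percentVolumeMap()`, `annualize()`,
  `smoothChangeMap()`;
* `assembleDesign()`, `fitVoxelwise()`, `attenuationReport()`,
  `bhCriticalP()`, `thresholdMaps()`, `analysisMask()`;
* `genotypePercentages()`, `contingencyChi2()`, `groupAnova()`,
  `wmVolumeRegression()`, `demographicsTable()`;
* `readVolume()` / `writeVolume()` (NIfTI-1), `readCovariates()` /
  `writeCovariates()` (TSV), and `runConfig()` / `runPipeline()` for the
  full chain. A thin CLI lives at `inst/scripts/phantom-tbm.R`.

## Worked example

A small cross-sectional cohort — 24 subjects on a 32³ grid with the
default −6 %/allele white-matter implant — runs in a few seconds:

```r
library(phantomTBM)
cfg <- runConfig(seed = 7, n = 24, gridShape = c(32, 32, 32),
                 outDir = "run1")
m <- runPipeline(cfg)
m$summary
#>   model  n df critical_p n_surviving peak_abs_beta mean_dose_beta_region
#> 1  base 24 20 0.01453748        1992      10.71042             -5.362682
```

Reading the row: the voxel-wise dose regression survived FDR at q = 0.05
up to a critical p-value of 0.0145 (1992 voxels); the mean dose beta over
the implanted white-matter region is −5.36 %/allele against an implanted
−6 — the pipeline recovered the ground truth to within the attenuation
registration regularization is expected to produce (the methods vignette
quantifies this). `peak_abs_beta` is the
largest surviving |β|; isolated peaks exceed the regional mean because
per-subject nuisance warps add local scatter. `run1/` holds the template
and dose-beta NIfTI volumes, the covariate TSV, a `report.tsv`, and a
`manifest.json` with a config hash, per-stage timings and warnings.

Scalar-level statistics mirror the genotype-split cohort tables:

```r
genotypePercentages(149, 157, 53)
#> percent_tt percent_ct
#>       14.8       43.7
contingencyChi2(matrix(c(92, 57, 103, 54, 36, 17), 3, 2, byrow = TRUE))$chi2
#> [1] 0.8437099
```

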