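Package: phantomTBM
Title: Tensor-Based Morphometry with Synthetic Phantom Cohorts for
    Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end tensor-based morphometry (TBM) pipeline for
    voxel-wise imaging-genetics association studies, exercised on
    synthetic brain phantoms with known ground truth. Provides a
    deterministic nested-ellipsoid phantom generator with implantable
    allele-dose volume effects and a homocysteine mediation pathway,
    diffusion-regularized demons nonlinear registration with an
    inverse-consistent symmetric mode, minimal deformation template
    construction, Jacobian-determinant volume-change maps
    (cross-sectional and annualized longitudinal), mass-univariate
    additive allele-dose regression with covariate adjustment,
    Benjamini-Hochberg false discovery rate thresholding with critical
    p-value reporting, and genotype-group demographic statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
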