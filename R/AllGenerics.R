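# Accessor generics and show methods.

#' @title Accessors for phantomTBM objects
#' @description Small accessor family: grid shape, voxel size, and the
#'   underlying arrays of templates, fields and maps.
#' @param object a phantomTBM S4 object.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("intensityVolume", function(object) standardGeneric("intensityVolume"))
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))
#' @rdname accessors
#' @export
setGeneric("jacobian", function(object) standardGeneric("jacobian"))
#' @rdname accessors
#' @export
setGeneric("changeValues", function(object) standardGeneric("changeValues"))
#' @rdname accessors
#' @export
setGeneric("changeMode", function(object) standardGeneric("changeMode"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("criticalP", function(object) standardGeneric("criticalP"))

#' @rdname accessors
#' @export
setMethod("gridShape", "PhantomTemplate", function(object) dim(object@labels))
#' @rdname accessors
#' @export
setMethod("gridShape", "DisplacementField", function(object) dim(object@u)[1:3])
#' @rdname accessors
#' @export
setMethod("gridShape", "JacobianMap", function(object) dim(object@j))
#' @rdname accessors
#' @export
setMethod("gridShape", "ChangeMap", function(object) dim(object@values))

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomTemplate", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DisplacementField", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "JacobianMap", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ChangeMap", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("intensityVolume", "PhantomTemplate", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("labelVolume", "PhantomTemplate", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("displacement", "DisplacementField", function(object) object@u)
#' @rdname accessors
#' @export
setMethod("jacobian", "JacobianMap", function(object) object@j)
#' @rdname accessors
#' @export
setMethod("changeValues", "ChangeMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("changeMode", "ChangeMap", function(object) object@mode)
#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@X)
#' @rdname accessors
#' @export
setMethod("criticalP", "FDRResult", function(object) object@criticalP)

#' Extract one statistical map from a voxel-wise fit
#'
#' @param object a \linkS4class{StatMapSet}.
#' @param predictor predictor name, e.g. \code{"dose"}.
#' @param what one of \code{"beta"}, \code{"se"}, \code{"t"}, \code{"p"}.
#' @return 3D numeric array (NA outside the analysis mask).
#' @export
setGeneric("statMap", function(object, predictor, what = "beta")
  standardGeneric("statMap"))

#' @rdname statMap
#' @export
setMethod("statMap", "StatMapSet", function(object, predictor, what = "beta") {
  if (!predictor %in% object@predictors)
    stop("unknown predictor '", predictor, "'; available: ",
         paste(object@predictors, collapse = ", "))
  what <- match.arg(what, c("beta", "se", "t", "p"))
  slot(object, c(beta = "beta", se = "se", t = "tstat", p = "pval")[[what]])[[predictor]]
})

setMethod("show", "PhantomTemplate", function(object) {
  d <- gridShape(object)
  counts <- table(factor(object@labels, levels = 0:4))
  cat("PhantomTemplate ", paste(d, collapse = " x "),
      " @ ", object@voxelSize, " mm\n", sep = "")
  cat("  labels (bg, GM, WM, ventricle, brainstem): ",
      paste(counts, collapse = ", "), "\n", sep = "")
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(rowSums(matrix(object@u, ncol = 3)^2))
  cat("DisplacementField ", paste(gridShape(object), collapse = " x "),
      "; |u| mean ", signif(mean(mag), 3), ", max ", signif(max(mag), 3),
      " voxels\n", sep = "")
})

setMethod("show", "JacobianMap", function(object) {
  cat("JacobianMap ", paste(gridShape(object), collapse = " x "),
      "; range [", signif(min(object@j), 4), ", ", signif(max(object@j), 4),
      "], clamped ", object@clampedCount, "\n", sep = "")
})

setMethod("show", "ChangeMap", function(object) {
  unit <- if (object@mode == "annualized") "%/yr" else "%"
  cat("ChangeMap (", object@mode, ") ",
      paste(gridShape(object), collapse = " x "),
      "; range [", signif(min(object@values), 4), ", ",
      signif(max(object@values), 4), "] ", unit, "\n", sep = "")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix ", nrow(object@X), " x ", ncol(object@X),
      " (", object@model, "): ", paste(colnames(object@X), collapse = ", "),
      "\n", sep = "")
  if (length(object@droppedIds))
    cat("  dropped (incomplete): ", length(object@droppedIds), "\n", sep = "")
})

setMethod("show", "StatMapSet", function(object) {
  cat("StatMapSet: ", paste(object@predictors, collapse = ", "),
      "; n = ", object@n, ", df = ", object@df,
      ", valid voxels = ", sum(object@valid), "/", sum(object@mask),
      "\n", sep = "")
})

setMethod("show", "FDRResult", function(object) {
  cat("FDRResult: q = ", object@q, ", m = ", object@m,
      ", critical p = ", signif(object@criticalP, 4),
      ", surviving = ", object@nSurviving, "\n", sep = "")
})
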