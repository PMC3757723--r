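# NIfTI-1 volume and tab-separated covariate I/O.

#' Write a volume as NIfTI-1
#'
#' Identity-orientation affine scaled by the voxel size. An optional
#' sidecar JSON records map mode, smoothing and provenance next to the
#' volume.
#'
#' @param vol 3D array, \linkS4class{PhantomTemplate} (intensity),
#'   \linkS4class{JacobianMap} or \linkS4class{ChangeMap}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize voxel edges in mm (scalar or length 3).
#' @param sidecar optional named list written to \code{<path>.json}.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path, voxelSize = NULL, sidecar = NULL) {
  if (is(vol, "PhantomTemplate")) {
    if (is.null(voxelSize)) voxelSize <- voxelSize(vol)
    vol <- intensityVolume(vol)
  } else if (is(vol, "JacobianMap")) {
    if (is.null(voxelSize)) voxelSize <- voxelSize(vol)
    vol <- jacobian(vol)
  } else if (is(vol, "ChangeMap")) {
    if (is.null(voxelSize)) voxelSize <- voxelSize(vol)
    vol <- changeValues(vol)
  }
  if (is.null(voxelSize)) voxelSize <- 1
  vs <- rep_len(voxelSize, 3)
  vol <- vol + 0                      # drop any class, keep a plain array
  attr(vol, "pixdim") <- vs
  img <- RNifti::asNifti(vol, datatype = "double")
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Volumes with a non-canonical on-disk orientation are reoriented to the
#' canonical (RAS) axis order with a logged note; the returned array uses
#' 0-based axis-aligned voxel indexing like everything else in the
#' package.
#'
#' @param path NIfTI file.
#' @return list with \code{volume} (3D array) and \code{voxelSize}
#'   (length 3, mm).
#' @export
readVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA)
  if (!is.na(orient) && !identical(orient, "RAS")) {
    message("readVolume: reorienting '", path, "' from ", orient, " to RAS")
    RNifti::orientation(img) <- "RAS"
  }
  vs <- RNifti::pixdim(img)[1:3]
  vol <- array(as.double(img), dim = dim(img)[1:3])
  list(volume = vol, voxelSize = vs)
}

covariateColumns <- c("subject_id", "dose", "age", "sex", "hcy", "folate",
                      "apoe4", "interval_months")

#' Write a covariate table
#'
#' Tab-separated with the canonical header; missing values are written as
#' empty fields. Sex is coded 0 = female, 1 = male.
#'
#' @param records data.frame of subject covariates.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCovariates <- function(records, path) {
  missing <- setdiff(covariateColumns, names(records))
  for (m in missing) records[[m]] <- NA
  write.table(records[, covariateColumns], path, sep = "\t", na = "",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Expects the tab-separated header written by
#' \code{\link{writeCovariates}}. Empty fields become NA (usable in the
#' base model only, via the complete-case rule); invalid doses are
#' rejected with their line number; duplicate subject ids are rejected.
#'
#' @param path input path.
#' @return data.frame of typed subject records.
#' @export
readCovariates <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "")
  missing <- setdiff(c("subject_id", "dose", "age", "sex"), names(df))
  if (length(missing))
    stop("covariate table lacks required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(is.na(df$dose) | !(df$dose %in% 0:2))
  if (length(bad))
    stop("invalid dose (must be 0, 1 or 2) on line ", bad[1] + 1L,
         " of ", path)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1])
  df$dose <- as.integer(df$dose)
  df$sex <- as.integer(df$sex)
  df
}
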