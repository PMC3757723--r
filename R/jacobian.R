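#' Jacobian determinant of a displacement field
#'
#' Computes \code{det(I + grad u)} by central differences (one-sided at
#' the faces). Values below the positivity floor \code{clampFloor} are
#' clamped, and the number of clamped voxels is recorded on the returned
#' map; a field clamping more than \code{maxClampedFrac} of interior
#' voxels is rejected as invalid.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param clampFloor positivity floor for the determinant.
#' @param maxClampedFrac maximum tolerated fraction of clamped interior
#'   voxels before rejection.
#' @return a \linkS4class{JacobianMap}.
#' @export
jacobianDeterminant <- function(field, clampFloor = 1e-3,
                                maxClampedFrac = 0.01) {
  comp <- compFromField(field)
  d <- dim(comp[[1]])
  j <- array(cpp_jacobian_det(as.double(comp[[1]]), as.double(comp[[2]]),
                              as.double(comp[[3]]), as.integer(d)), dim = d)
  interior <- interiorMask(d)
  nClamped <- sum(j[interior] < clampFloor)
  if (nClamped > maxClampedFrac * sum(interior))
    stop("field invalid: ", nClamped, " interior voxels (",
         signif(100 * nClamped / sum(interior), 3),
         "%) fall below the Jacobian floor; stronger regularization needed")
  if (nClamped > 0)
    message("jacobianDeterminant: clamped ", nClamped, " voxels at ",
            clampFloor)
  j[j < clampFloor] <- clampFloor
  new("JacobianMap", j = j, voxelSize = voxelSize(field),
      clampedCount = as.integer(nClamped))
}

#' Percent volume-change map from a Jacobian map
#'
#' \code{c = (j - 1) * 100}: a determinant of 0.94 is a 6 percent local
#' volume deficit relative to the template; 1.12 a 12 percent expansion.
#'
#' @param jac a \linkS4class{JacobianMap}.
#' @return a cross-sectional \linkS4class{ChangeMap}.
#' @export
percentVolumeMap <- function(jac) {
  stopifnot(is(jac, "JacobianMap"))
  new("ChangeMap", values = (jacobian(jac) - 1) * 100,
      mode = "cross_sectional", voxelSize = voxelSize(jac))
}

#' Annualize a baseline-to-follow-up change map
#'
#' Rescales a cross-sectional percent change measured over an interval to
#' percent per year: \code{c * 12 / interval_months}.
#'
#' @param change a cross-sectional \linkS4class{ChangeMap} from a
#'   baseline-to-follow-up registration.
#' @param intervalMonths scan interval, in \code{[6, 24]} months.
#' @return an annualized \linkS4class{ChangeMap}.
#' @export
annualize <- function(change, intervalMonths) {
  stopifnot(is(change, "ChangeMap"))
  if (changeMode(change) != "cross_sectional")
    stop("annualize expects a cross_sectional map")
  if (intervalMonths < 6 || intervalMonths > 24)
    stop("intervalMonths must lie in [6, 24]")
  new("ChangeMap", values = changeValues(change) * 12 / intervalMonths,
      mode = "annualized", voxelSize = voxelSize(change))
}

#' Gaussian smoothing of a change map
#'
#' Applied before voxel-wise statistics to stabilize per-voxel estimates.
#'
#' @param change a \linkS4class{ChangeMap}.
#' @param sigma Gaussian width in voxels (default 1.5).
#' @return the smoothed \linkS4class{ChangeMap}.
#' @export
smoothChangeMap <- function(change, sigma = 1.5) {
  stopifnot(is(change, "ChangeMap"))
  new("ChangeMap", values = smooth3D(changeValues(change), sigma),
      mode = changeMode(change), voxelSize = voxelSize(change))
}
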