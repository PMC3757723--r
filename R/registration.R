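#' Registration configuration constructor
#'
#' Defaults suit the phantom scale used throughout the package: a
#' three-level pyramid, moderate diffusion regularization, and sub-voxel
#' step caps. Symmetric mode estimates forward and backward fields
#' jointly and averages them antisymmetrically (inverse-consistent).
#'
#' @param nLevels,itersPerLevel,updateSigma,fieldSigma,stepCap,symmetric,tol
#'   see \linkS4class{RegistrationConfig}.
#' @return a \linkS4class{RegistrationConfig}.
#' @export
registrationConfig <- function(nLevels = 3L, itersPerLevel = c(100L, 60L, 40L),
                               updateSigma = 2, fieldSigma = 0.8,
                               stepCap = 0.8, symmetric = FALSE, tol = 1e-4) {
  new("RegistrationConfig", nLevels = as.integer(nLevels),
      itersPerLevel = as.integer(rep_len(itersPerLevel, nLevels)),
      updateSigma = updateSigma, fieldSigma = fieldSigma,
      stepCap = stepCap, symmetric = symmetric, tol = tol)
}

asVolumeArray <- function(x) {
  if (is(x, "PhantomTemplate")) return(intensityVolume(x))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a 3D array or PhantomTemplate")
}

# Trilinear resampling of a volume to a new grid (used by the pyramid).
resampleVolume <- function(vol, newDim) {
  d <- dim(vol)
  f <- d / newDim
  g <- coordGrids(newDim)
  xs <- (g$x + 0.5) * f[1] - 0.5
  ys <- (g$y + 0.5) * f[2] - 0.5
  zs <- (g$z + 0.5) * f[3] - 0.5
  array(cpp_sample_trilinear(as.double(vol), as.integer(d), xs, ys, zs, 0),
        dim = newDim)
}

# Upsample a displacement field (list of 3 component arrays), scaling the
# displacements by the per-axis resolution factor.
prolongField <- function(comp, newDim) {
  d <- dim(comp[[1]])
  f <- newDim / d
  lapply(1:3, function(i) resampleVolume(comp[[i]], newDim) * f[i])
}

zeroShell <- function(arr) {
  d <- dim(arr)
  array(cpp_zero_shell(as.double(arr), as.integer(d)), dim = d)
}

warpArr <- function(vol, comp) {
  d <- dim(vol)
  array(cpp_warp_field(as.double(vol), as.integer(d),
                       as.double(comp[[1]]), as.double(comp[[2]]),
                       as.double(comp[[3]]), 0), dim = d)
}

zeroField <- function(d) lapply(1:3, function(i) array(0, dim = d))

# One demons loop at a fixed resolution. Returns the field components and
# the accepted SSD trace (non-increasing by construction: a worsening
# update is reverted and iteration stops).
demonsLevel <- function(fixed, moving, comp, iters, config) {
  d <- dim(fixed)
  trace <- numeric(0)
  prevSsd <- Inf
  prevComp <- comp
  for (it in seq_len(iters)) {
    warped <- warpArr(moving, comp)
    upd <- cpp_demons_update(as.double(fixed), as.double(warped),
                             as.integer(d), config@stepCap)
    ssd <- upd$ssd
    if (ssd > prevSsd) {
      comp <- prevComp
      break
    }
    trace <- c(trace, ssd)
    if (is.finite(prevSsd) &&
        (prevSsd - ssd) / max(prevSsd, 1e-12) < config@tol) {
      prevSsd <- ssd
      break
    }
    prevSsd <- ssd
    prevComp <- comp
    dc <- list(array(upd$dx, dim = d), array(upd$dy, dim = d),
               array(upd$dz, dim = d))
    if (config@updateSigma > 0)
      dc <- lapply(dc, smooth3D, sigma = config@updateSigma)
    comp <- lapply(1:3, function(i) comp[[i]] + dc[[i]])
    if (config@fieldSigma > 0)
      comp <- lapply(comp, smooth3D, sigma = config@fieldSigma)
    comp <- lapply(comp, zeroShell)
  }
  list(comp = comp, trace = trace, ssd = prevSsd)
}

invertComp <- function(comp, iters = 10L) {
  d <- dim(comp[[1]])
  inv <- lapply(comp, function(a) -a)
  for (it in seq_len(iters)) {
    s <- lapply(1:3, function(i)
      array(cpp_warp_field(as.double(comp[[i]]), as.integer(d),
                           as.double(inv[[1]]), as.double(inv[[2]]),
                           as.double(inv[[3]]), 0), dim = d))
    inv <- lapply(1:3, function(i) -s[[i]])
  }
  inv
}

fieldFromComp <- function(comp, voxelSize) {
  d <- dim(comp[[1]])
  new("DisplacementField",
      u = array(c(comp[[1]], comp[[2]], comp[[3]]), dim = c(d, 3)),
      voxelSize = voxelSize)
}

compFromField <- function(field) {
  u <- displacement(field)
  lapply(1:3, function(i) u[, , , i])
}

#' Demons nonlinear registration
#'
#' Diffusion-regularized demons: at each iteration the intensity
#' difference between the fixed image and the warped moving image drives a
#' Thirion update (difference times warped-image gradient over squared
#' gradient magnitude plus squared difference), which is Gaussian-smoothed
#' (\code{updateSigma}), capped at \code{stepCap} voxels, added to the
#' field, after which the field itself is smoothed (\code{fieldSigma}) and
#' forced to zero on the outermost voxel shell. The schedule is coarse to
#' fine over \code{nLevels}. In symmetric mode, forward and backward
#' fields are estimated jointly and periodically averaged with each
#' other's numerical inverse, which enforces inverse consistency.
#'
#' @param moving,fixed 3D arrays (or \linkS4class{PhantomTemplate}s) on
#'   the same grid, affinely pre-aligned.
#' @param config a \linkS4class{RegistrationConfig}.
#' @param voxelSize voxel edge in mm recorded on the returned field.
#' @param both return both directions as
#'   \code{list(forward, backward)}; in asymmetric mode the backward field
#'   is estimated by an independent reverse-direction registration.
#' @return a \linkS4class{DisplacementField} on the fixed grid (the
#'   transform maps fixed coordinates x to moving coordinates x + u(x)),
#'   with attribute \code{ssdTrace}; or a two-field list when
#'   \code{both = TRUE}.
#' @export
registerNonlinear <- function(moving, fixed, config = registrationConfig(),
                              voxelSize = 1, both = FALSE) {
  validObject(config)
  moving <- asVolumeArray(moving)
  fixed <- asVolumeArray(fixed)
  if (!identical(dim(moving), dim(fixed)))
    stop("moving and fixed volumes must share a grid")
  if (config@symmetric)
    return(registerSymmetric(moving, fixed, config, voxelSize, both))
  d <- dim(fixed)
  dims <- lapply(rev(seq_len(config@nLevels) - 1L),
                 function(p) pmax(as.integer(ceiling(d / 2^p)), 8L))
  comp <- NULL
  trace <- list()
  for (lv in seq_len(config@nLevels)) {
    dl <- dims[[lv]]
    fx <- if (all(dl == d)) fixed else resampleVolume(fixed, dl)
    mv <- if (all(dl == d)) moving else resampleVolume(moving, dl)
    comp <- if (is.null(comp)) zeroField(dl) else prolongField(comp, dl)
    res <- demonsLevel(fx, mv, comp, config@itersPerLevel[lv], config)
    comp <- res$comp
    trace[[lv]] <- res$trace
  }
  jac <- cpp_jacobian_det(as.double(comp[[1]]), as.double(comp[[2]]),
                          as.double(comp[[3]]), as.integer(d))
  interior <- interiorMask(d)
  if (any(jac[interior] <= 0))
    stop("registration produced a folding field (non-positive Jacobian); ",
         "increase fieldSigma/updateSigma or reduce stepCap")
  out <- fieldFromComp(comp, voxelSize)
  attr(out, "ssdTrace") <- trace
  if (!both) return(out)
  bwd <- registerNonlinear(fixed, moving, config, voxelSize, both = FALSE)
  list(forward = out, backward = bwd)
}

registerSymmetric <- function(moving, fixed, config, voxelSize, both) {
  cfgAsym <- config
  cfgAsym@symmetric <- FALSE
  d <- dim(fixed)
  dims <- lapply(rev(seq_len(config@nLevels) - 1L),
                 function(p) pmax(as.integer(ceiling(d / 2^p)), 8L))
  fcomp <- bcomp <- NULL
  traceF <- list()
  for (lv in seq_len(config@nLevels)) {
    dl <- dims[[lv]]
    fx <- if (all(dl == d)) fixed else resampleVolume(fixed, dl)
    mv <- if (all(dl == d)) moving else resampleVolume(moving, dl)
    fcomp <- if (is.null(fcomp)) zeroField(dl) else prolongField(fcomp, dl)
    bcomp <- if (is.null(bcomp)) zeroField(dl) else prolongField(bcomp, dl)
    iters <- config@itersPerLevel[lv]
    chunk <- 5L
    done <- 0L
    while (done < iters) {
      k <- min(chunk, iters - done)
      resF <- demonsLevel(fx, mv, fcomp, k, config)
      resB <- demonsLevel(mv, fx, bcomp, k, config)
      fcomp <- resF$comp
      bcomp <- resB$comp
      # antisymmetric averaging with the other direction's inverse
      invB <- invertComp(bcomp)
      invF <- invertComp(fcomp)
      fcomp <- lapply(1:3, function(i) 0.5 * (fcomp[[i]] + invB[[i]]))
      bcomp <- lapply(1:3, function(i) 0.5 * (bcomp[[i]] + invF[[i]]))
      traceF[[length(traceF) + 1L]] <- resF$trace
      done <- done + k
      if (length(resF$trace) < k && length(resB$trace) < k) break
    }
  }
  jac <- cpp_jacobian_det(as.double(fcomp[[1]]), as.double(fcomp[[2]]),
                          as.double(fcomp[[3]]), as.integer(d))
  if (any(jac[interiorMask(d)] <= 0))
    stop("registration produced a folding field (non-positive Jacobian)")
  fwd <- fieldFromComp(fcomp, voxelSize)
  attr(fwd, "ssdTrace") <- traceF
  if (!both) return(fwd)
  list(forward = fwd, backward = fieldFromComp(bcomp, voxelSize))
}

#' Affine registration by sum-of-squared-differences descent
#'
#' Estimates an affine transform mapping fixed-grid coordinates to moving
#' coordinates, \code{y = A (x - c) + c + t} about the volume center c,
#' by BFGS minimization of the SSD between the warped moving image and
#' the fixed image over a two-level pyramid. \code{dof = 9} parameterizes
#' translation, rotation and per-axis log-scales; \code{dof = 12} a full
#' linear map plus translation.
#'
#' @param moving,fixed 3D arrays (or \linkS4class{PhantomTemplate}s).
#' @param dof 9 or 12.
#' @return list with elements \code{A} (3x3), \code{t} (length 3),
#'   \code{center}, \code{ssd} (final value), \code{initialSsd}.
#' @export
registerAffine <- function(moving, fixed, dof = 12L) {
  moving <- asVolumeArray(moving)
  fixed <- asVolumeArray(fixed)
  if (!identical(dim(moving), dim(fixed)))
    stop("moving and fixed volumes must share a grid")
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("volumes must have nonzero intensity variance")
  if (!dof %in% c(9L, 12L)) stop("dof must be 9 or 12")
  d <- dim(fixed)
  center <- (d - 1) / 2

  par2affine <- function(p) {
    t <- p[1:3]
    if (dof == 9L) {
      ang <- p[4:6]
      Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                  c(0, sin(ang[1]), cos(ang[1])))
      Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                  c(-sin(ang[2]), 0, cos(ang[2])))
      Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                  c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
      A <- Rz %*% Ry %*% Rx %*% diag(exp(p[7:9]))
    } else {
      A <- diag(3) + matrix(p[4:12], 3, 3)
    }
    list(A = A, t = t)
  }

  ssdAt <- function(p, fx, mv, dl) {
    tr <- par2affine(p)
    g <- coordGrids(dl)
    f <- d / dl        # level coords -> full-resolution coords
    cx <- (g$x + 0.5) * f[1] - 0.5 - center[1]
    cy <- (g$y + 0.5) * f[2] - 0.5 - center[2]
    cz <- (g$z + 0.5) * f[3] - 0.5 - center[3]
    xs <- tr$A[1, 1] * cx + tr$A[1, 2] * cy + tr$A[1, 3] * cz + center[1] + tr$t[1]
    ys <- tr$A[2, 1] * cx + tr$A[2, 2] * cy + tr$A[2, 3] * cz + center[2] + tr$t[2]
    zs <- tr$A[3, 1] * cx + tr$A[3, 2] * cy + tr$A[3, 3] * cz + center[3] + tr$t[3]
    # back to level coordinates for sampling the level image
    xs <- (xs + 0.5) / f[1] - 0.5
    ys <- (ys + 0.5) / f[2] - 0.5
    zs <- (zs + 0.5) / f[3] - 0.5
    w <- cpp_sample_trilinear(as.double(mv), as.integer(dl), xs, ys, zs, 0)
    sum((w - as.double(fx))^2)
  }

  p <- rep(0, if (dof == 9L) 9 else 12)
  levels <- list(pmax(as.integer(ceiling(d / 2)), 8L), d)
  sigmas <- c(2, 1)
  init <- NA
  for (lv in seq_along(levels)) {
    dl <- levels[[lv]]
    fx <- smooth3D(if (all(dl == d)) fixed else resampleVolume(fixed, dl), sigmas[lv])
    mv <- smooth3D(if (all(dl == d)) moving else resampleVolume(moving, dl), sigmas[lv])
    if (lv == 1L) init <- ssdAt(p, fx, mv, dl)
    opt <- stats::optim(p, ssdAt, fx = fx, mv = mv, dl = dl, method = "BFGS",
                        control = list(maxit = 150, reltol = 1e-10,
                                       ndeps = rep(1e-4, length(p))))
    if (lv == 1L && opt$value > init + max(1e-8, 1e-9 * init))
      stop("affine registration diverged: SSD rose from ", signif(init, 6),
           " to ", signif(opt$value, 6), " at the coarse level")
    p <- opt$par
  }
  tr <- par2affine(p)
  finalFull <- ssdAt(p, smooth3D(fixed, 0), smooth3D(moving, 0), d)
  list(A = tr$A, t = tr$t, center = center, ssd = finalFull,
       initialSsd = sum((moving - fixed)^2))
}

#' Warp a volume through a displacement field
#'
#' Trilinear interpolation at \code{x + u(x)}; samples outside the grid
#' take the background value 0.
#'
#' @param vol 3D array (or \linkS4class{PhantomTemplate}).
#' @param field a \linkS4class{DisplacementField} on the same grid.
#' @param nearest use nearest-neighbour interpolation (label volumes).
#' @return 3D array on the fixed grid.
#' @export
warpVolume <- function(vol, field, nearest = FALSE) {
  vol <- asVolumeArray(vol)
  comp <- compFromField(field)
  if (!identical(dim(vol), dim(comp[[1]])))
    stop("volume and field grids do not match")
  d <- dim(vol)
  fun <- if (nearest) cpp_warp_field_nn else cpp_warp_field
  array(fun(as.double(vol), as.integer(d), as.double(comp[[1]]),
            as.double(comp[[2]]), as.double(comp[[3]]), 0), dim = d)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration: \code{v(x) = -u(x + v(x))}.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param iters number of fixed-point iterations.
#' @return the inverse \linkS4class{DisplacementField}.
#' @export
invertField <- function(field, iters = 10L) {
  comp <- compFromField(field)
  fieldFromComp(invertComp(comp, iters), voxelSize(field))
}

#' Mean inverse-consistency error of a field pair
#'
#' Mean over interior voxels of the residual
#' \code{|| u_fwd(x + u_bwd(x)) + u_bwd(x) ||} in voxels: zero when the
#' two transforms are exact mutual inverses.
#'
#' @param fwd,bwd \linkS4class{DisplacementField}s on the same grid.
#' @return scalar, voxels.
#' @export
inverseConsistencyError <- function(fwd, bwd) {
  cf <- compFromField(fwd)
  cb <- compFromField(bwd)
  if (!identical(dim(cf[[1]]), dim(cb[[1]])))
    stop("fields must share a grid")
  d <- dim(cf[[1]])
  res <- lapply(1:3, function(i)
    array(cpp_warp_field(as.double(cf[[i]]), as.integer(d),
                         as.double(cb[[1]]), as.double(cb[[2]]),
                         as.double(cb[[3]]), 0), dim = d) + cb[[i]])
  mag <- sqrt(res[[1]]^2 + res[[2]]^2 + res[[3]]^2)
  # restrict to interior voxels whose displaced sample stays on the grid
  g <- coordGrids(d)
  inGrid <- g$x + cb[[1]] >= 0 & g$x + cb[[1]] <= d[1] - 1 &
    g$y + cb[[2]] >= 0 & g$y + cb[[2]] <= d[2] - 1 &
    g$z + cb[[3]] >= 0 & g$z + cb[[3]] <= d[3] - 1
  sel <- interiorMask(d) & array(inGrid, dim = d)
  mean(mag[sel])
}

#' Build a minimal deformation template
#'
#' Iterates: register every volume to the current reference, average the
#' warped images, then compose that mean image with the inverse of the
#' average displacement so the template sits at the group's geometric
#' center (the average deformation from members to the template is driven
#' toward zero).
#'
#' @param volumes list of >= 3 aligned 3D arrays.
#' @param nIter number of template update iterations.
#' @param config a \linkS4class{RegistrationConfig}.
#' @param voxelSize voxel edge in mm.
#' @return list with elements \code{mdt} (3D array), \code{fields} (final
#'   per-subject \linkS4class{DisplacementField}s to the returned
#'   template) and \code{meanDisplacement} (mean magnitude of the average
#'   field per iteration, voxels).
#' @export
buildMDT <- function(volumes, nIter = 2L, config = registrationConfig(),
                     voxelSize = 1) {
  if (length(volumes) < 3L) stop("need at least 3 volumes")
  volumes <- lapply(volumes, asVolumeArray)
  d <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), d), logical(1))))
    stop("all volumes must share a grid")
  ref <- Reduce(`+`, volumes) / length(volumes)
  meanDisp <- numeric(nIter)
  fields <- NULL
  for (it in seq_len(nIter)) {
    fields <- lapply(seq_along(volumes), function(i) {
      tryCatch(registerNonlinear(volumes[[i]], ref, config, voxelSize),
               error = function(e)
                 stop("registration failed for member ", i, ": ",
                      conditionMessage(e)))
    })
    warped <- mapply(function(v, f) warpVolume(v, f), volumes, fields,
                     SIMPLIFY = FALSE)
    meanImg <- Reduce(`+`, warped) / length(warped)
    avg <- lapply(1:3, function(k)
      Reduce(`+`, lapply(fields, function(f) displacement(f)[, , , k])) /
        length(fields))
    meanDisp[it] <- mean(sqrt(avg[[1]]^2 + avg[[2]]^2 + avg[[3]]^2))
    inv <- invertComp(avg)
    ref <- warpArr(meanImg, inv)
  }
  # fields returned are to the final (recentered) template
  fields <- lapply(seq_along(volumes), function(i)
    registerNonlinear(volumes[[i]], ref, config, voxelSize))
  list(mdt = ref, fields = fields, meanDisplacement = meanDisp)
}
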