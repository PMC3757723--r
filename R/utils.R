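# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Stable 32-bit FNV-1a hash of a character string, folded into [0, 2^31).
# Used to derive independent per-subject RNG streams from one run seed.
stableHash <- function(x) {
  bytes <- as.integer(charToRaw(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply by the FNV prime mod 2^32 without exceeding 2^53
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

subjectSeed <- function(baseSeed, subjectId, salt = 0L) {
  as.integer((as.numeric(baseSeed) + as.numeric(stableHash(paste0(subjectId, ":", salt)))) %%
               2147483647)
}

# Gaussian smoothing of a 3D array (separable, truncated at 3 sigma).
smooth3D <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  array(cpp_smooth3(as.double(vol), as.integer(d), as.double(sigma)), dim = d)
}

# Elliptical radius of 0-based voxel coordinates about a center.
ellipRadiusGrid <- function(gridShape, center, radii) {
  ix <- (seq_len(gridShape[1]) - 1 - center[1]) / radii[1]
  iy <- (seq_len(gridShape[2]) - 1 - center[2]) / radii[2]
  iz <- (seq_len(gridShape[3]) - 1 - center[3]) / radii[3]
  sqrt(outer(outer(ix^2, iy^2, "+"), iz^2, "+"))
}

# 0-based voxel coordinate grids as vectors aligned with array storage.
coordGrids <- function(gridShape) {
  list(
    x = rep(seq_len(gridShape[1]) - 1, times = gridShape[2] * gridShape[3]),
    y = rep(rep(seq_len(gridShape[2]) - 1, each = gridShape[1]), times = gridShape[3]),
    z = rep(seq_len(gridShape[3]) - 1, each = gridShape[1] * gridShape[2])
  )
}

interiorMask <- function(gridShape, margin = 1L) {
  m <- array(FALSE, dim = gridShape)
  m[(1 + margin):(gridShape[1] - margin),
    (1 + margin):(gridShape[2] - margin),
    (1 + margin):(gridShape[3] - margin)] <- TRUE
  m
}

# 6-neighbourhood binary dilation of a logical 3D array.
dilate6 <- function(mask, iterations = 1L) {
  d <- dim(mask)
  out <- mask
  for (it in seq_len(iterations)) {
    nb <- out
    nb[-1, , ] <- nb[-1, , ] | out[-d[1], , ]
    nb[-d[1], , ] <- nb[-d[1], , ] | out[-1, , ]
    nb[, -1, ] <- nb[, -1, ] | out[, -d[2], ]
    nb[, -d[2], ] <- nb[, -d[2], ] | out[, -1, ]
    nb[, , -1] <- nb[, , -1] | out[, , -d[3]]
    nb[, , -d[3]] <- nb[, , -d[3]] | out[, , -1]
    out <- nb
  }
  out
}

# FNV-1a hash of an R object's JSON serialization (configuration hashes).
configHash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", stableHash(as.character(js)))
}
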