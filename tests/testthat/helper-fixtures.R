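# Shared fixtures, built once per test run.

smallTemplate <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- makeTemplatePhantom(c(32L, 32L, 32L))
    tpl
  }
})

midTemplate <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- makeTemplatePhantom(c(40L, 40L, 40L))
    tpl
  }
})

subjectRecord <- function(id = "S1", dose = 0L, age = 75, sex = 1L,
                          hcy = 10.2, folate = 500, apoe4 = 0L,
                          interval = NA_real_) {
  data.frame(subject_id = id, dose = as.integer(dose), age = age,
             sex = as.integer(sex), hcy = hcy, folate = folate,
             apoe4 = as.integer(apoe4), interval_months = interval,
             stringsAsFactors = FALSE)
}

quietEffect <- function(...) effectSpec(nuisanceWarpMM = 0, noiseSD = 0, ...)

constantField <- function(d, v = c(0, 0, 0), voxelSize = 1) {
  u <- array(0, dim = c(d, 3))
  for (i in 1:3) u[, , , i] <- v[i]
  new("DisplacementField", u = u, voxelSize = voxelSize)
}

# A smooth random displacement field (white noise smoothed and scaled).
smoothRandomField <- function(d, amplitude = 0.5, sigma = 3, seed = 1) {
  set.seed(seed)
  comp <- lapply(1:3, function(i) {
    f <- phantomTBM:::smooth3D(array(rnorm(prod(d)), dim = d), sigma)
    f <- f / sd(f) * amplitude
    phantomTBM:::zeroShell(f)
  })
  u <- array(c(comp[[1]], comp[[2]], comp[[3]]), dim = c(d, 3))
  new("DisplacementField", u = u, voxelSize = 1)
}

# Resample a volume under a uniform scaling s about the grid center.
scaledVolume <- function(vol, s) {
  d <- dim(vol)
  ctr <- (d - 1) / 2
  g <- phantomTBM:::coordGrids(d)
  array(phantomTBM:::cpp_sample_trilinear(
    as.double(vol), as.integer(d),
    (g$x - ctr[1]) / s + ctr[1], (g$y - ctr[2]) / s + ctr[2],
    (g$z - ctr[3]) / s + ctr[3], 0), dim = d)
}
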