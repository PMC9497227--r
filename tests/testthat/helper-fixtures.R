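# Shared fixtures, all built in code.

# small cohort configuration on a coarse grid (3 mm voxels) so that unit
# tests stay fast; study-structure parameters keep their defaults
tinyConfig <- function(nPerGroup = c(ASIB = 2L, FXS = 2L, LRC = 2L),
                       seed = 42L, ...) {
  cohortConfig(nPerGroup = nPerGroup, gridDim = 61L, voxelSize = 3,
               seed = seed, ...)
}

# analytic shell model without any voxel fitting
directShell <- function(radii = c(brain = 60, csf = 65, skull = 70,
                                  scalp = 78),
                        cond = c(brain = 0.33, csf = 1.79, skull = 0.0132,
                                 scalp = 0.35),
                        order = 60L) {
  new("ShellModel", center = c(0, 0, 0), radii = radii,
      conductivities = cond, order = as.integer(order), residual = 0)
}

# label volume of exact concentric spheres (no ellipsoidal anisotropy)
sphereVolume <- function(radii = c(60, 65, 70, 78), voxelSize = 2,
                         gridDim = 91L) {
  half <- (gridDim - 1) / 2
  ax <- seq(-half, half) * voxelSize
  re <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  codes <- c(background = 0L, white = 1L, gray = 2L, csf = 3L,
             skull = 4L, scalp = 5L)
  lab <- array(codes[["background"]], dim = rep(gridDim, 3L))
  lab[re <= radii[4]] <- codes[["scalp"]]
  lab[re <= radii[3]] <- codes[["skull"]]
  lab[re <= radii[2]] <- codes[["csf"]]
  lab[re <= radii[1]] <- codes[["gray"]]
  lab[re <= 0.55 * radii[1]] <- codes[["white"]]
  new("TissueVolume", data = lab, voxelSize = voxelSize,
      origin = rep(-half * voxelSize, 3), labels = codes)
}

# electrodes spread over the full sphere (for forward-model symmetry and
# oracle checks, where montage realism is irrelevant)
sphereElectrodes <- function(n = 40L, radius = 78, seed = 7L) {
  set.seed(seed)
  u <- matrix(rnorm(n * 3), ncol = 3)
  u / sqrt(rowSums(u^2)) * radius
}

# small two-group cohort shared by several test files (built once)
.cachedCohort <- local({
  cache <- NULL
  function(noiseSd = 0) {
    key <- as.character(noiseSd)
    if (is.null(cache[[key]]))
      cache[[key]] <<- makeCohort(tinyConfig(noiseSd = noiseSd),
                                  sourceStride = 2L)
    cache[[key]]
  }
})
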