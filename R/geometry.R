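# Synthetic layered head geometry, shell-model reduction and ROI atlas.
#
# Geometry is deliberately simple: concentric ellipsoidal layers on a coarse
# isotropic grid. The pipeline needs controlled between-subject and
# between-template geometric variation, not anatomical realism.

# fixed per-axis semi-axis multipliers (x = right, y = anterior,
# z = superior); distinct values keep principal axes well defined for the
# rigid alignment step
.headAnisotropy <- c(0.95, 1.06, 0.99)

# white matter core as a fraction of the brain radii; the rim between this
# and the brain boundary is gray matter and hosts the ROI atlas
.whiteFraction <- 0.55

.tissueCodes <- c(background = 0L, white = 1L, gray = 2L, csf = 3L,
                  skull = 4L, scalp = 5L)

# shell index per tissue (1 = innermost compartment, 5 = outside the head),
# used for boundary extraction and occupancy-tie resolution
.shellIndex <- c(background = 5L, white = 1L, gray = 1L, csf = 2L,
                 skull = 3L, scalp = 4L)

#' Build a tissue label volume of concentric ellipsoidal layers
#'
#' @param radii named numeric length-4: nominal outer radii (mm) for
#'   \code{brain, csf, skull, scalp}, strictly increasing.
#' @param voxelSize voxel edge (mm).
#' @param gridDim odd integer, voxels per axis.
#' @return a \linkS4class{TissueVolume} with labels
#'   \code{background, white, gray, csf, skull, scalp}.
#' @export
makeLayeredVolume <- function(radii, voxelSize = 2, gridDim = 91L) {
  stopifnot(length(radii) == 4L, all(diff(radii) > 0), gridDim %% 2L == 1L)
  half <- (gridDim - 1) / 2
  ax <- seq(-half, half) * voxelSize
  a <- .headAnisotropy
  # effective radial coordinate after undoing the anisotropy
  r2 <- outer(outer((ax / a[1])^2, (ax / a[2])^2, "+"), (ax / a[3])^2, "+")
  re <- sqrt(r2)
  lab <- array(.tissueCodes[["background"]], dim = rep(gridDim, 3L))
  lab[re <= radii[4]] <- .tissueCodes[["scalp"]]
  lab[re <= radii[3]] <- .tissueCodes[["skull"]]
  lab[re <= radii[2]] <- .tissueCodes[["csf"]]
  lab[re <= radii[1]] <- .tissueCodes[["gray"]]
  lab[re <= .whiteFraction * radii[1]] <- .tissueCodes[["white"]]
  new("TissueVolume", data = lab, voxelSize = voxelSize,
      origin = rep(-half * voxelSize, 3L), labels = .tissueCodes)
}

#' Draw one subject's head geometry
#'
#' Shell radii are drawn per subject as the group mean plus Gaussian
#' jitter: one shared head-size deviate with the group's full SD applied
#' to all four shells (head size covaries across shells) plus a smaller
#' independent per-shell deviate (a quarter of the SD), both truncated at
#' two standard deviations. Draws that compress any shell below ~70% of a
#' voxel are rejected and redrawn a bounded number of times, then error.
#'
#' @param group group label present in \code{config$nPerGroup}.
#' @param config a \code{\link{cohortConfig}}.
#' @param maxRetry bounded redraw count for ordering violations.
#' @return a \linkS4class{TissueVolume}.
#' @export
makeSubjectGeometry <- function(group, config, maxRetry = 50L) {
  if (!group %in% names(config$nPerGroup))
    stop("unknown group: ", group)
  mu <- config$geometryMean[[group]]
  sd <- config$geometrySd[[group]]
  trunc2 <- function(x, s) pmin(pmax(x, -2 * s), 2 * s)
  for (i in seq_len(maxRetry)) {
    common <- trunc2(stats::rnorm(1L, 0, sd), sd)
    shellJit <- trunc2(stats::rnorm(4L, 0, sd / 4), sd / 4)
    radii <- mu + common + shellJit
    if (all(diff(radii) >= 0.7 * config$voxelSize))
      return(makeLayeredVolume(radii, config$voxelSize, config$gridDim))
  }
  stop("could not draw strictly increasing shell radii for group ", group,
       " after ", maxRetry, " attempts")
}

# logical mask of the brain compartment (gray + white)
.brainMask <- function(volume) {
  lab <- labelData(volume)
  lm <- labelMap(volume)
  lab == lm[["gray"]] | lab == lm[["white"]]
}

# per-voxel shell index (1 brain, 2 csf, 3 skull, 4 scalp, 5 outside)
.shellIndexArray <- function(volume) {
  lab <- labelData(volume)
  lm <- labelMap(volume)
  idx <- array(5L, dim = dim(lab))
  for (nm in names(lm)) {
    if (nm %in% names(.shellIndex))
      idx[lab == lm[[nm]]] <- .shellIndex[[nm]]
  }
  idx
}

# voxels of shell s with a 6-neighbour of a strictly outer shell
.outerBoundaryMask <- function(shellIdx, s) {
  d <- dim(shellIdx)
  inS <- shellIdx == s
  outer <- shellIdx > s
  nb <- array(FALSE, dim = d)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, dim = d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by == 1L) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else          { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1L, -1L))
    nb <- nb | shift(outer, ax, by)
  inS & nb
}

#' Reduce a tissue volume to a four-shell spherical head model
#'
#' The model centre is the centroid of the scalp compartment; each shell
#' radius is the mean centre distance of that compartment's outer boundary
#' voxels plus half a voxel (boundary voxel centres sit, on average, half a
#' voxel inside the interface). The RMS spread of boundary distances about
#' the fitted radii is recorded as the fit residual.
#'
#' @param volume a \linkS4class{TissueVolume} with brain, CSF, skull and
#'   scalp compartments.
#' @param table conductivity table, see \code{\link{defaultConductivities}};
#'   the brain shell takes the gray-matter value.
#' @param order Legendre series truncation order for downstream lead
#'   fields.
#' @return a \linkS4class{ShellModel}.
#' @export
fitShellModel <- function(volume, table = defaultConductivities(),
                          order = 60L) {
  shellIdx <- .shellIndexArray(volume)
  if (!all(1:4 %in% shellIdx))
    stop("volume is missing a compartment: need brain, csf, skull, scalp")
  coords <- voxelCoordinates(volume)
  scalpSel <- which(shellIdx == 4L)
  center <- colMeans(coords[scalpSel, , drop = FALSE])
  radii <- numeric(4L)
  ss <- 0
  nb <- 0L
  for (s in 1:4) {
    bd <- which(.outerBoundaryMask(shellIdx, s))
    if (!length(bd)) stop("compartment ", s, " has no boundary voxels")
    dst <- sqrt(rowSums(sweep(coords[bd, , drop = FALSE], 2, center)^2))
    radii[s] <- mean(dst) + voxelSize(volume) / 2
    ss <- ss + sum((dst + voxelSize(volume) / 2 - radii[s])^2)
    nb <- nb + length(bd)
  }
  names(radii) <- c("brain", "csf", "skull", "scalp")
  need <- c("gray", "csf", "skull", "scalp")
  if (!all(need %in% names(table)))
    stop("conductivity table must name: ", paste(need, collapse = ", "))
  cond <- stats::setNames(unname(table[need]),
                          c("brain", "csf", "skull", "scalp"))
  new("ShellModel", center = unname(center), radii = radii,
      conductivities = cond, order = as.integer(order),
      residual = sqrt(ss / nb))
}

# canonical ROI directions (unit-ish vectors, x = right, y = anterior,
# z = superior) and laterality; bilateral ROIs get mirrored +/- x centres
.roiTable <- function() {
  m <- rbind(
    dorsal_anterior_cingulate  = c(0.00,  0.60,  0.55),
    ventral_anterior_cingulate = c(0.00,  0.70,  0.10),
    posterior_cingulate        = c(0.00, -0.50,  0.45),
    frontal_pole               = c(0.25,  0.90,  0.05),
    orbital_frontal            = c(0.45,  0.80, -0.35),
    temporal_pole              = c(0.85,  0.35, -0.30),
    superior_temporal_gyrus    = c(0.90, -0.10,  0.05),
    superior_temporal_sulcus   = c(0.92, -0.25, -0.12),
    middle_temporal            = c(0.90, -0.35, -0.28),
    parahippocampal            = c(0.45, -0.35, -0.50),
    anterior_fusiform          = c(0.50, -0.50, -0.55),
    middle_fusiform            = c(0.55, -0.68, -0.48),
    lingual_gyrus              = c(0.20, -0.82, -0.35),
    lateral_inferior_occipital = c(0.75, -0.80, -0.28),
    medial_inferior_occipital  = c(0.30, -0.95, -0.28),
    middle_occipital           = c(0.60, -0.90, -0.02),
    superior_occipital         = c(0.35, -0.90,  0.35),
    superior_parietal          = c(0.35, -0.55,  0.80)
  )
  dirs <- m / sqrt(rowSums(m^2))
  list(directions = dirs, bilateral = dirs[, 1] != 0)
}

# march along direction u from center until leaving the brain compartment;
# returns the distance (mm) of the last brain-labelled sample
.brainExtent <- function(brain, volume, center, u) {
  v <- voxelSize(volume)
  d <- dim(brain)
  o <- gridOrigin(volume)
  steps <- seq(0, max(d) * v, by = v / 2)
  last <- 0
  for (t in steps) {
    p <- center + t * u
    ijk <- round((p - o) / v) + 1
    if (any(ijk < 1) || any(ijk > d)) break
    if (brain[ijk[1], ijk[2], ijk[3]]) last <- t else if (t > 0) break
  }
  last
}

#' Carve an 18-ROI atlas out of the gray-matter compartment
#'
#' Each ROI is the set of gray-matter voxels within \code{roiRadius} of the
#' ROI centre, with overlaps resolved to the nearest centre; bilateral ROIs
#' have mirrored left/right centres carrying one label, so the atlas is
#' exactly symmetric under left-right grid reflection when the geometry is.
#' Centres sit at \code{depthFraction} of the brain extent along canonical
#' anatomical directions.
#'
#' @param geometry a \linkS4class{TissueVolume} with a brain compartment.
#' @param roiRadius sphere radius (mm) around each ROI centre.
#' @param depthFraction radial position of centres as a fraction of the
#'   brain extent along the ROI direction.
#' @return a \linkS4class{RoiAtlas}.
#' @export
makeRoiAtlas <- function(geometry, roiRadius = 7, depthFraction = 0.65) {
  brain <- .brainMask(geometry)
  if (!any(brain)) stop("geometry has no brain compartment")
  lm <- labelMap(geometry)
  grayMask <- labelData(geometry) == lm[["gray"]]
  coords <- voxelCoordinates(geometry)
  center <- colMeans(coords[as.vector(brain), , drop = FALSE])
  tab <- .roiTable()
  centres <- list()   # per ROI: matrix of 1 or 2 centre rows
  for (i in seq_len(nrow(tab$directions))) {
    u <- tab$directions[i, ]
    ext <- .brainExtent(brain, geometry, center, u)
    p <- center + depthFraction * ext * u
    if (tab$bilateral[i]) {
      um <- u * c(-1, 1, 1)
      extm <- .brainExtent(brain, geometry, center, um)
      pm <- center + depthFraction * extm * um
      centres[[i]] <- rbind(p, pm)
    } else centres[[i]] <- rbind(p)
  }
  graySel <- which(as.vector(grayMask))
  gcoords <- coords[graySel, , drop = FALSE]
  best <- rep(Inf, length(graySel))
  lab <- rep(0L, length(graySel))
  for (i in seq_along(centres)) {
    for (r in seq_len(nrow(centres[[i]]))) {
      d2 <- (gcoords[, 1] - centres[[i]][r, 1])^2 +
            (gcoords[, 2] - centres[[i]][r, 2])^2 +
            (gcoords[, 3] - centres[[i]][r, 3])^2
      hit <- d2 <= roiRadius^2 & d2 < best
      best[hit] <- d2[hit]
      lab[hit] <- i
    }
  }
  arr <- array(0L, dim = dim(labelData(geometry)))
  arr[graySel] <- lab
  counts <- tabulate(lab, nbins = length(centres))
  if (any(counts == 0L))
    stop("brain compartment too small to host all ROIs; empty: ",
         paste(rownames(tab$directions)[counts == 0L], collapse = ", "))
  roiNames <- stats::setNames(seq_along(centres), rownames(tab$directions))
  vols <- stats::setNames(counts * voxelSize(geometry)^3,
                          rownames(tab$directions))
  new("RoiAtlas", data = arr, voxelSize = voxelSize(geometry),
      origin = gridOrigin(geometry), roiNames = roiNames, roiVolumes = vols)
}

#' Source grid from an atlas
#'
#' Source positions are ROI-interior voxel centres at a configurable
#' stride.
#'
#' @param atlas a \linkS4class{RoiAtlas}.
#' @param stride keep every \code{stride}-th voxel along each axis.
#' @return list with \code{positions} (n x 3 mm) and \code{roi} (integer
#'   codes).
#' @export
sourceGridFromAtlas <- function(atlas, stride = 1L) {
  arr <- labelData(atlas)
  d <- dim(arr)
  sel <- which(arr > 0L)
  if (stride > 1L) {
    k <- (sel - 1L) %/% (d[1] * d[2])
    rem <- (sel - 1L) %% (d[1] * d[2])
    j <- rem %/% d[1]
    i <- rem %% d[1]
    keep <- i %% stride == 0L & j %% stride == 0L & k %% stride == 0L
    sel <- sel[keep]
  }
  coords <- voxelCoordinates(atlas)
  list(positions = coords[sel, , drop = FALSE],
       roi = as.integer(arr[sel]))
}
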