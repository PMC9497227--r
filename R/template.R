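# Average-template construction: rigid (optionally similarity) alignment
# by centroid and principal axes of the head, label-occupancy averaging,
# and the iterative align-average-converge loop with an RMS-difference
# stopping rule.

# tie-break priority when relabelling averaged occupancy: outermost wins
.labelPriority <- function(labels) {
  pri <- .shellIndex[names(labels)]
  pri[is.na(pri)] <- 0L
  order(pri, decreasing = TRUE)
}

.headMask <- function(volume) labelData(volume) != 0L

#' Rigid alignment of one head volume to another
#'
#' Estimates rotation + translation (optionally uniform scale) taking the
#' moving volume's head onto the reference's, from centroid matching and
#' principal-axis alignment of the scalp-bounded head region. Degenerate
#' principal axes (near-spherical head) fall back to the identity rotation
#' with a warning.
#'
#' @param moving,reference \linkS4class{TissueVolume}s on the same voxel
#'   size.
#' @param allowScale also estimate a uniform scale (flagged in the
#'   result).
#' @return list of class \code{head_transform}: \code{rotation} (3x3),
#'   \code{translation} (length 3), \code{scale}, \code{scaled} flag;
#'   maps world coordinates as \code{x_ref = scale * R x_mov + translation}.
#' @export
rigidAlign <- function(moving, reference, allowScale = FALSE) {
  if (abs(voxelSize(moving) - voxelSize(reference)) > 1e-9)
    stop("volumes must share a voxel size")
  axes <- function(vol) {
    sel <- which(as.vector(.headMask(vol)))
    x <- voxelCoordinates(vol)[sel, , drop = FALSE]
    ctr <- colMeans(x)
    cv <- stats::cov(x)
    e <- eigen(cv, symmetric = TRUE)
    v <- e$vectors
    for (k in 1:2) {   # deterministic sign convention
      m <- which.max(abs(v[, k]))
      if (v[m, k] < 0) v[, k] <- -v[, k]
    }
    v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
                v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
                v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
    list(center = ctr, vectors = v, values = e$values,
         spread = sqrt(mean(rowSums(sweep(x, 2, ctr)^2))))
  }
  mv <- axes(moving)
  rf <- axes(reference)
  gaps <- function(ev) min(diff(-ev) / ev[1])
  if (gaps(mv$values) < 1e-3 || gaps(rf$values) < 1e-3) {
    warning("near-degenerate principal axes; using identity rotation")
    rot <- diag(3)
  } else {
    rot <- rf$vectors %*% t(mv$vectors)
  }
  s <- if (allowScale) rf$spread / mv$spread else 1
  list(rotation = rot,
       translation = rf$center - s * as.numeric(rot %*% mv$center),
       scale = s, scaled = allowScale) |>
    structure(class = "head_transform")
}

#' Resample a label volume through a head transform
#'
#' Nearest-neighbour resampling of \code{volume} onto \code{grid}'s voxel
#' grid after applying the transform; voxels mapping outside the source
#' grid become background.
#'
#' @param volume a \linkS4class{TissueVolume}.
#' @param transform a \code{head_transform} from \code{\link{rigidAlign}}.
#' @param grid volume defining the target grid (defaults to
#'   \code{volume}).
#' @return a \linkS4class{TissueVolume} on the target grid.
#' @export
applyTransform <- function(volume, transform, grid = volume) {
  W <- voxelCoordinates(grid)
  S <- sweep(W, 2, transform$translation) %*% transform$rotation /
    transform$scale
  v <- voxelSize(volume)
  d <- dim(labelData(volume))
  idx <- round(sweep(S, 2, gridOrigin(volume)) / v) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(W))
  lin <- (idx[ok, 3] - 1L) * d[1] * d[2] + (idx[ok, 2] - 1L) * d[1] +
    idx[ok, 1]
  out[ok] <- labelData(volume)[lin]
  new("TissueVolume", data = array(out, dim = dim(labelData(grid))),
      voxelSize = voxelSize(grid), origin = gridOrigin(grid),
      labels = labelMap(volume))
}

# one-hot occupancy matrix (voxels x labels)
.occupancy <- function(arr, labels) {
  out <- matrix(0, length(arr), length(labels))
  colnames(out) <- names(labels)
  for (i in seq_along(labels)) out[, i] <- as.numeric(arr == labels[[i]])
  out
}

#' Build an average head-model template
#'
#' Iterative align-average-converge: at iteration k every input volume is
#' rigidly aligned to the previous reference, per-label occupancy
#' fractions are averaged, and the average is re-labelled by argmax (ties
#' broken toward the outermost tissue). The RMS voxelwise occupancy
#' difference between successive references is tracked, and iteration
#' stops when it levels (|RMS_k - RMS_(k-1)| < tol), when it vanishes
#' (RMS_k < tol), or at \code{maxIter} (returned with
#' \code{converged = FALSE}). The first input serves as the initial
#' reference.
#'
#' @param volumes list of \linkS4class{TissueVolume}s on a shared grid.
#' @param tol stopping tolerance in occupancy units.
#' @param maxIter iteration cap.
#' @param allowScale estimate uniform scale during alignment.
#' @return a \linkS4class{TemplateModel}.
#' @export
buildAverageTemplate <- function(volumes, tol = 1e-3, maxIter = 10L,
                                 allowScale = FALSE) {
  if (!length(volumes)) stop("need at least one input volume")
  labels <- labelMap(volumes[[1]])
  ref <- volumes[[1]]
  if (length(volumes) == 1L)
    return(new("TemplateModel", volume = ref, transforms = list(),
               rmsTrace = 0, nIterations = 1L, converged = TRUE))
  occPrev <- .occupancy(as.vector(labelData(ref)), labels)
  prio <- .labelPriority(labels)
  rms <- numeric(0)
  transforms <- list()
  converged <- FALSE
  for (k in seq_len(maxIter)) {
    occ <- matrix(0, nrow(occPrev), ncol(occPrev))
    transforms <- vector("list", length(volumes))
    for (i in seq_along(volumes)) {
      transforms[[i]] <- rigidAlign(volumes[[i]], ref, allowScale)
      aligned <- applyTransform(volumes[[i]], transforms[[i]], ref)
      occ <- occ + .occupancy(as.vector(labelData(aligned)), labels)
    }
    occ <- occ / length(volumes)
    colnames(occ) <- names(labels)
    rms[k] <- sqrt(mean((occ - occPrev)^2))
    # argmax relabel with outermost-wins tie-break
    win <- prio[max.col(occ[, prio, drop = FALSE], ties.method = "first")]
    lab <- array(unname(labels[win]), dim = dim(labelData(ref)))
    ref <- new("TissueVolume", data = lab, voxelSize = voxelSize(ref),
               origin = gridOrigin(ref), labels = labels)
    occPrev <- occ
    if (rms[k] < tol || (k >= 2 && abs(rms[k] - rms[k - 1]) < tol)) {
      converged <- TRUE
      break
    }
  }
  new("TemplateModel", volume = ref, transforms = transforms,
      rmsTrace = rms, nIterations = length(rms), converged = converged)
}
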