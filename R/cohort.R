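# Synthetic cohort generation: configuration, dipole source specification,
# ERP simulation through the subject's own lead field, and cohort assembly.
#
# The generator encodes the statistical structure the downstream analysis
# assumes: three groups (ASIB, FXS, LRC) with group-dependent head size and
# heterogeneity (ASIB most heterogeneous), four stimulus conditions whose
# N290 generators sit in fusiform/parahippocampal ROIs, faces > toys
# source amplitude in every group, and group scaling FXS > LRC > ASIB.

#' Cohort configuration
#'
#' @param nPerGroup named integer vector, subjects per group; defaults to
#'   the study-sized cohort of 21 ASIB, 15 FXS and 21 LRC.
#' @param geometryMean named list of length-4 numeric vectors, per-group
#'   mean outer shell radii (mm) for brain/CSF/skull/scalp.
#' @param geometrySd named numeric, per-group radius jitter SD (mm);
#'   larger for ASIB than FXS, encoding the greater geometric
#'   heterogeneity of that group.
#' @param effectSizes named numeric, condition -> N290 source amplitude
#'   multiplier; both face conditions exceed both toy conditions.
#' @param groupScale named numeric, group -> N290 source amplitude
#'   multiplier (FXS enhanced, ASIB muted, LRC intermediate).
#' @param noiseSd additive white sensor noise SD, uV.
#' @param samplingRate Hz.
#' @param epochWindow length-2 ms, epoch start (negative = baseline) and
#'   end relative to stimulus onset.
#' @param voxelSize mm. @param gridDim odd voxel count per axis.
#' @param seed integer seed stamped into the cohort.
#' @return a list of class \code{cohort_config}.
#' @export
cohortConfig <- function(nPerGroup = c(ASIB = 21L, FXS = 15L, LRC = 21L),
                         geometryMean = list(
                           ASIB = c(brain = 60, csf = 66, skull = 72, scalp = 78),
                           FXS  = c(brain = 59, csf = 65, skull = 71, scalp = 77),
                           LRC  = c(brain = 58, csf = 64, skull = 70, scalp = 76)),
                         geometrySd = c(ASIB = 3, FXS = 1.5, LRC = 2),
                         effectSizes = c(mother_face = 1.05,
                                         stranger_face = 0.95,
                                         own_toy = 0.65, novel_toy = 0.55),
                         groupScale = c(ASIB = 0.7, FXS = 1.4, LRC = 1.0),
                         noiseSd = 0.5, samplingRate = 250,
                         epochWindow = c(-100, 600), voxelSize = 2,
                         gridDim = 91L, seed = 1L) {
  groups <- names(nPerGroup)
  stopifnot(all(nPerGroup >= 1L),
            all(groups %in% names(geometryMean)),
            all(groups %in% names(geometrySd)),
            noiseSd >= 0, samplingRate > 0,
            epochWindow[1] < 0, epochWindow[2] > 400)
  for (g in groups)
    if (any(diff(geometryMean[[g]]) <= 0))
      stop("geometryMean radii must be strictly increasing for group ", g)
  cond <- c("mother_face", "stranger_face", "own_toy", "novel_toy")
  if (!all(cond %in% names(effectSizes)))
    stop("effectSizes must name all four conditions")
  structure(list(nPerGroup = nPerGroup, geometryMean = geometryMean,
                 geometrySd = geometrySd, effectSizes = effectSizes,
                 groupScale = groupScale, noiseSd = noiseSd,
                 samplingRate = samplingRate, epochWindow = epochWindow,
                 voxelSize = voxelSize, gridDim = as.integer(gridDim),
                 seed = as.integer(seed), conditions = cond),
            class = "cohort_config")
}

#' Default dipole source specification
#'
#' Dipole generators of the simulated ERP: a positive P1 component from
#' bilateral medial inferior occipital sources (peak ~130 ms) and a
#' negative N290 component from bilateral middle fusiform, anterior
#' fusiform and parahippocampal sources (peak ~290 ms). Dipoles are
#' radially oriented; N290 dipoles point inward so nearby posterior
#' electrodes see a negative deflection. Time courses are Gaussian bumps,
#' which makes peak-latency assertions exact. Condition and group
#' multipliers apply to the N290-component sources.
#'
#' @param atlas a \linkS4class{RoiAtlas}; source positions are the
#'   centroids of the listed ROIs' left and right parts.
#' @return data.frame with one dipole per row: \code{roi, x, y, z, ox, oy,
#'   oz} (unit orientation), \code{component, latency_ms, width_ms,
#'   moment_nAm}.
#' @export
defaultSourceSpec <- function(atlas) {
  spec <- rbind(
    data.frame(roi = "medial_inferior_occipital", component = "P1",
               latency_ms = 130, width_ms = 40, moment_nAm = 20,
               inward = FALSE),
    data.frame(roi = "middle_fusiform", component = "N290",
               latency_ms = 290, width_ms = 40, moment_nAm = 30,
               inward = TRUE),
    data.frame(roi = "anterior_fusiform", component = "N290",
               latency_ms = 290, width_ms = 44, moment_nAm = 22,
               inward = TRUE),
    data.frame(roi = "parahippocampal", component = "N290",
               latency_ms = 290, width_ms = 44, moment_nAm = 20,
               inward = TRUE)
  )
  arr <- labelData(atlas)
  coords <- voxelCoordinates(atlas)
  nm <- roiNames(atlas)
  out <- NULL
  for (i in seq_len(nrow(spec))) {
    code <- nm[[spec$roi[i]]]
    sel <- which(as.vector(arr) == code)
    pos <- coords[sel, , drop = FALSE]
    for (side in c(-1, 1)) {   # left / right part of the bilateral ROI
      p <- pos[sign(pos[, 1]) == side | pos[, 1] == 0, , drop = FALSE]
      if (!nrow(p)) next
      ctr <- colMeans(p)
      o <- ctr / sqrt(sum(ctr^2))
      if (spec$inward[i]) o <- -o
      out <- rbind(out, data.frame(
        roi = spec$roi[i], x = ctr[1], y = ctr[2], z = ctr[3],
        ox = o[1], oy = o[2], oz = o[3], component = spec$component[i],
        latency_ms = spec$latency_ms[i], width_ms = spec$width_ms[i],
        moment_nAm = spec$moment_nAm[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate per-condition ERP averages through a lead field
#'
#' Each condition's waveform is the lead field applied to the summed
#' Gaussian-windowed dipole time courses, with the N290-component dipole
#' moments scaled by the condition effect size and the group multiplier,
#' plus additive zero-mean white sensor noise, then average-referenced.
#'
#' @param sourceSpec dipole table (\code{\link{defaultSourceSpec}}).
#' @param leadField a \linkS4class{LeadField} for this subject's geometry
#'   and montage (its source grid is ignored; gains for the spec dipoles
#'   are computed from the same shell model), or a function
#'   \code{(positions) -> gain matrix}. Simplest is to pass the gains via
#'   \code{dipoleGain}.
#' @param dipoleGain numeric matrix, electrodes x (3 * n_dipoles): gains at
#'   the spec dipole positions.
#' @param group group label. @param config a \code{\link{cohortConfig}}.
#' @return named list condition -> \linkS4class{ErpAverage}.
#' @export
simulateErp <- function(sourceSpec, dipoleGain, group, config,
                        channels) {
  missing <- setdiff(config$conditions, names(config$effectSizes))
  if (length(missing))
    stop("effectSizes missing condition(s): ",
         paste(missing, collapse = ", "))
  dt <- 1000 / config$samplingRate
  tt <- seq(config$epochWindow[1], config$epochWindow[2] - dt, by = dt)
  nT <- length(tt)
  nD <- nrow(sourceSpec)
  stopifnot(ncol(dipoleGain) == 3L * nD)
  # per-dipole unit time course (Gaussian bump at the component latency)
  tc <- matrix(0, nD, nT)
  for (d in seq_len(nD))
    tc[d, ] <- exp(-0.5 * ((tt - sourceSpec$latency_ms[d]) /
                             (sourceSpec$width_ms[d] / 2))^2)
  ori <- as.matrix(sourceSpec[, c("ox", "oy", "oz")])
  out <- list()
  for (cnd in config$conditions) {
    scale <- ifelse(sourceSpec$component == "N290",
                    config$effectSizes[[cnd]] * config$groupScale[[group]],
                    1)
    mom <- sourceSpec$moment_nAm * scale
    # moment time courses stacked as (3 nD) x nT
    M <- matrix(0, 3L * nD, nT)
    for (d in seq_len(nD))
      M[(3 * d - 2):(3 * d), ] <- outer(ori[d, ] * mom[d], tc[d, ])
    v <- dipoleGain %*% M
    if (config$noiseSd > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, config$noiseSd), nrow(v))
    v <- sweep(v, 2, colMeans(v))   # average reference
    out[[cnd]] <- new("ErpAverage", data = v, channels = channels,
                      samplingRate = config$samplingRate,
                      t0 = config$epochWindow[1], condition = cnd,
                      group = group, reference = "average")
  }
  out
}

#' Generate a seeded synthetic cohort
#'
#' For every subject: draw the layered head geometry, fit the four-shell
#' model, place the electrodes, compute the Self lead field on the shared
#' atlas source grid, and simulate the four-condition ERP averages through
#' the subject's own head model. The atlas and dipole specification are
#' built once on the canonical (LRC-mean, zero-jitter) geometry so that
#' ROI values are comparable across subjects and head models.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param sourceStride stride of the atlas source grid.
#' @param keepGeometry keep each subject's TissueVolume (memory heavy for
#'   large cohorts; shell models are always kept).
#' @return list of class \code{cohort} with elements \code{config},
#'   \code{atlas}, \code{sourceGrid}, \code{sourceSpec}, \code{template}
#'   (montage template), and \code{subjects} (list with id, group, shell,
#'   montage, leadField, erp, and optionally geometry).
#' @export
makeCohort <- function(config = cohortConfig(), sourceStride = 1L,
                       keepGeometry = FALSE) {
  set.seed(config$seed)
  canon <- makeLayeredVolume(config$geometryMean[["LRC"]],
                             config$voxelSize, config$gridDim)
  atlas <- makeRoiAtlas(canon)
  grid <- sourceGridFromAtlas(atlas, stride = sourceStride)
  spec <- defaultSourceSpec(atlas)
  tmpl <- defaultMontageTemplate()
  subjects <- list()
  for (grp in names(config$nPerGroup)) {
    for (i in seq_len(config$nPerGroup[[grp]])) {
      geom <- makeSubjectGeometry(grp, config)
      shell <- fitShellModel(geom)
      montage <- placeElectrodes(shell, tmpl)
      lf <- computeLeadField(shell, montage, grid)
      dipGain <- .dipoleGains(shell, montage, spec)
      erp <- simulateErp(spec, dipGain, grp, config,
                         electrodeNames(montage))
      subj <- list(id = sprintf("%s_%02d", grp, i), group = grp,
                   shell = shell, montage = montage, leadField = lf,
                   erp = erp)
      if (keepGeometry) subj$geometry <- geom
      subjects[[subj$id]] <- subj
    }
  }
  structure(list(config = config, atlas = atlas, sourceGrid = grid,
                 sourceSpec = spec, template = tmpl, subjects = subjects),
            class = "cohort")
}

# gains of the spec dipoles under a given head model
.dipoleGains <- function(shell, montage, sourceSpec) {
  pos <- as.matrix(sourceSpec[, c("x", "y", "z")])
  gainMatrix(computeLeadField(shell, montage, pos))
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:",
      paste(sprintf("%s=%d", names(x$config$nPerGroup),
                    x$config$nPerGroup), collapse = ", "),
      sprintf("| %d sources, seed %d\n",
              nrow(x$sourceGrid$positions), x$config$seed))
  invisible(x)
}
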