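#' @import methods
NULL

#' Tissue label volume
#'
#' Integer voxel grid of tissue classes on a regular, axis-aligned grid in
#' world millimetres. Label codes are mapped to tissue names by the
#' \code{labels} slot; code 0 is always background. World coordinates of
#' voxel \code{(i, j, k)} (1-based) are
#' \code{origin + (c(i, j, k) - 1) * voxelSize}.
#'
#' @slot data integer 3D array of label codes.
#' @slot voxelSize numeric scalar, edge length of a voxel in mm (isotropic).
#' @slot origin numeric length-3, world mm coordinate of the centre of the
#'   first voxel.
#' @slot labels named integer vector mapping tissue name to label code;
#'   must include \code{background = 0}.
#' @exportClass TissueVolume
setClass("TissueVolume",
  representation(
    data = "array",
    voxelSize = "numeric",
    origin = "numeric",
    labels = "integer"
  )
)

setValidity("TissueVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a positive scalar (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (is.null(names(object@labels)) || any(!nzchar(names(object@labels))))
    msg <- c(msg, "labels must be a named integer vector")
  if (!"background" %in% names(object@labels) ||
      object@labels[["background"]] != 0L)
    msg <- c(msg, "labels must map background to 0")
  codes <- unique(as.integer(object@data))
  if (length(setdiff(codes, object@labels)) > 0)
    msg <- c(msg, "data contains codes absent from the label map")
  if (length(msg)) msg else TRUE
})

#' Region-of-interest atlas
#'
#' Label volume of named, mutually exclusive regions of interest carved out
#' of the gray-matter compartment of a \linkS4class{TissueVolume}, on the
#' same grid. Per-ROI volumes (mm^3) are recorded at construction.
#'
#' @slot data integer 3D array of ROI codes (0 = no ROI).
#' @slot voxelSize numeric scalar, mm.
#' @slot origin numeric length-3, world mm.
#' @slot roiNames named integer vector mapping ROI name to code.
#' @slot roiVolumes named numeric vector, ROI volume in mm^3.
#' @exportClass RoiAtlas
setClass("RoiAtlas",
  representation(
    data = "array",
    voxelSize = "numeric",
    origin = "numeric",
    roiNames = "integer",
    roiVolumes = "numeric"
  )
)

setValidity("RoiAtlas", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (is.null(names(object@roiNames)))
    msg <- c(msg, "roiNames must be named")
  if (!setequal(names(object@roiVolumes), names(object@roiNames)))
    msg <- c(msg, "roiVolumes must be named like roiNames")
  if (any(object@roiVolumes < 0)) msg <- c(msg, "roiVolumes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Four-shell spherical head model
#'
#' Reduction of a layered head geometry to four concentric spherical shells
#' (brain, CSF, skull, scalp) with piecewise-homogeneous conductivities,
#' used by the analytic Legendre-series forward solution. The brain shell
#' carries the gray-matter conductivity.
#'
#' @slot center numeric length-3, world mm.
#' @slot radii named numeric length-4, strictly increasing outer radii (mm)
#'   for \code{brain < csf < skull < scalp}.
#' @slot conductivities named numeric length-4, S/m, same order as radii.
#' @slot order integer, Legendre series truncation order (>= 20).
#' @slot residual numeric, RMS distance (mm) of compartment boundary voxels
#'   from the fitted shell radii.
#' @exportClass ShellModel
setClass("ShellModel",
  representation(
    center = "numeric",
    radii = "numeric",
    conductivities = "numeric",
    order = "integer",
    residual = "numeric"
  )
)

setValidity("ShellModel", function(object) {
  msg <- character()
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (length(object@radii) != 4L || any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be 4 strictly increasing values")
  if (length(object@conductivities) != 4L || any(object@conductivities <= 0))
    msg <- c(msg, "conductivities must be 4 positive values (S/m)")
  if (object@order < 20L) msg <- c(msg, "series order must be >= 20")
  if (length(msg)) msg else TRUE
})

#' Electrode montage
#'
#' Ordered scalp electrode positions in world mm, the fiducial anchors
#' (nasion, left/right preauricular), and the posterior electrode clusters
#' used for N290 measurement.
#'
#' @slot names character, electrode names in channel order.
#' @slot positions numeric matrix (n x 3), world mm on the scalp shell.
#' @slot clusters named list of character vectors, cluster name ->
#'   member electrode names.
#' @slot fiducials numeric 3 x 3 matrix, rows nasion/lpa/rpa, world mm.
#' @exportClass ElectrodeMontage
setClass("ElectrodeMontage",
  representation(
    names = "character",
    positions = "matrix",
    clusters = "list",
    fiducials = "matrix"
  )
)

setValidity("ElectrodeMontage", function(object) {
  msg <- character()
  if (nrow(object@positions) != length(object@names))
    msg <- c(msg, "positions must have one row per electrode")
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must have 3 columns")
  bad <- vapply(object@clusters,
                function(cl) any(!cl %in% object@names), logical(1))
  if (any(bad))
    msg <- c(msg, paste("clusters reference unknown electrodes:",
                        paste(names(object@clusters)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Lead field
#'
#' Linear gain matrix mapping dipole moments (nA*m) at candidate source
#' positions to average-referenced scalp potentials (uV). Each source
#' occupies three consecutive columns (free orientation, x/y/z moment).
#'
#' @slot gain numeric matrix, n_electrodes x (3 * n_sources), uV per nA*m.
#' @slot sourcePositions numeric matrix (n_sources x 3), world mm.
#' @slot sourceRoi integer vector, atlas ROI code per source (0 if none).
#' @slot electrodeNames character, row order of \code{gain}.
#' @slot order integer, series truncation order used.
#' @slot reference character, reference convention ("average").
#' @exportClass LeadField
setClass("LeadField",
  representation(
    gain = "matrix",
    sourcePositions = "matrix",
    sourceRoi = "integer",
    electrodeNames = "character",
    order = "integer",
    reference = "character"
  )
)

setValidity("LeadField", function(object) {
  msg <- character()
  if (ncol(object@gain) != 3L * nrow(object@sourcePositions))
    msg <- c(msg, "gain must have 3 columns per source")
  if (nrow(object@gain) != length(object@electrodeNames))
    msg <- c(msg, "gain must have one row per electrode")
  if (length(object@sourceRoi) != nrow(object@sourcePositions))
    msg <- c(msg, "sourceRoi must have one entry per source")
  if (any(!is.finite(object@gain)))
    msg <- c(msg, "gain must be finite")
  if (identical(object@reference, "average") && ncol(object@gain) > 0) {
    cs <- max(abs(colSums(object@gain)))
    ref <- max(abs(object@gain))
    if (cs > 1e-8 * max(ref, 1))
      msg <- c(msg, "average-referenced gain columns must sum to 0")
  }
  if (length(msg)) msg else TRUE
})

#' ERP average
#'
#' Per-condition channel-by-sample average waveform in microvolts, with the
#' sampling information needed to convert samples to post-stimulus
#' latencies.
#'
#' @slot data numeric matrix, channels x samples, uV.
#' @slot channels character, channel names (montage order).
#' @slot samplingRate numeric, Hz.
#' @slot t0 numeric, ms; time of the first sample relative to stimulus
#'   onset (negative = baseline before onset).
#' @slot condition character.
#' @slot group character.
#' @slot reference character, reference convention.
#' @exportClass ErpAverage
setClass("ErpAverage",
  representation(
    data = "matrix",
    channels = "character",
    samplingRate = "numeric",
    t0 = "numeric",
    condition = "character",
    group = "character",
    reference = "character"
  )
)

setValidity("ErpAverage", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "data must have one row per channel")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  tmax <- object@t0 + (ncol(object@data) - 1) * 1000 / object@samplingRate
  if (object@t0 > 0 || tmax < 0)
    msg <- c(msg, "stimulus onset (t = 0) must lie within the sampled interval")
  if (length(msg)) msg else TRUE
})

#' eLORETA inverse operator
#'
#' Resolution of the eLORETA inverse mapping for a given lead field: the
#' (3 * n_sources) x n_electrodes matrix taking average-referenced scalp
#' potentials (uV) to dipole moment estimates (nA*m), together with the
#' converged per-source 3x3 weight blocks and the convergence trace.
#'
#' @slot mapping numeric matrix, (3 * n_sources) x n_electrodes.
#' @slot weights numeric array, 3 x 3 x n_sources, symmetric
#'   positive-definite per source.
#' @slot alpha numeric, regularization relative to the mean sensor-space
#'   eigenvalue.
#' @slot trace numeric, max relative weight change per iteration.
#' @slot iterations integer.
#' @slot reference character.
#' @exportClass EloretaOperator
setClass("EloretaOperator",
  representation(
    mapping = "matrix",
    weights = "array",
    alpha = "numeric",
    trace = "numeric",
    iterations = "integer",
    reference = "character"
  )
)

setValidity("EloretaOperator", function(object) {
  msg <- character()
  if (nrow(object@mapping) %% 3L != 0L)
    msg <- c(msg, "mapping must have 3 rows per source")
  if (!identical(dim(object@weights)[1:2], c(3L, 3L)))
    msg <- c(msg, "weights must be a 3 x 3 x n_sources array")
  if (dim(object@weights)[3] * 3L != nrow(object@mapping))
    msg <- c(msg, "weights and mapping disagree on the number of sources")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Average head-model template
#'
#' Result of the iterative align-average-converge template construction:
#' the re-labelled average volume, the per-input alignment transforms of
#' the final iteration, and the RMS convergence trace.
#'
#' @slot volume a \linkS4class{TissueVolume}, the final template.
#' @slot transforms list of alignment transforms (one per input volume).
#' @slot rmsTrace numeric, RMS occupancy difference between successive
#'   reference volumes, one value per iteration.
#' @slot nIterations integer.
#' @slot converged logical.
#' @exportClass TemplateModel
setClass("TemplateModel",
  representation(
    volume = "TissueVolume",
    transforms = "list",
    rmsTrace = "numeric",
    nIterations = "integer",
    converged = "logical"
  )
)

setValidity("TemplateModel", function(object) {
  msg <- character()
  if (length(object@rmsTrace) != object@nIterations)
    msg <- c(msg, "rmsTrace length must equal nIterations")
  if (length(msg)) msg else TRUE
})
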