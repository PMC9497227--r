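# Generics, accessors and show methods for the core containers.

#' @name accessors
#' @title Accessors for erpsource containers
#' @description Small accessor layer over the S4 containers; user code
#'   should use these rather than reaching into slots.
#' @param object an erpsource S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("roiVolumes", function(object) standardGeneric("roiVolumes"))
#' @rdname accessors
#' @export
setGeneric("shellRadii", function(object) standardGeneric("shellRadii"))
#' @rdname accessors
#' @export
setGeneric("shellConductivities",
           function(object) standardGeneric("shellConductivities"))
#' @rdname accessors
#' @export
setGeneric("shellCenter", function(object) standardGeneric("shellCenter"))
#' @rdname accessors
#' @export
setGeneric("electrodeNames",
           function(object) standardGeneric("electrodeNames"))
#' @rdname accessors
#' @export
setGeneric("electrodePositions",
           function(object) standardGeneric("electrodePositions"))
#' @rdname accessors
#' @export
setGeneric("clusterMap", function(object) standardGeneric("clusterMap"))
#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(object) standardGeneric("gainMatrix"))
#' @rdname accessors
#' @export
setGeneric("sourcePositions",
           function(object) standardGeneric("sourcePositions"))
#' @rdname accessors
#' @export
setGeneric("sourceRoi", function(object) standardGeneric("sourceRoi"))
#' @rdname accessors
#' @export
setGeneric("erpData", function(object) standardGeneric("erpData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("timesMs", function(object) standardGeneric("timesMs"))
#' @rdname accessors
#' @export
setGeneric("inverseMapping", function(object) standardGeneric("inverseMapping"))
#' @rdname accessors
#' @export
setGeneric("sourceWeights", function(object) standardGeneric("sourceWeights"))
#' @rdname accessors
#' @export
setGeneric("rmsTrace", function(object) standardGeneric("rmsTrace"))
#' @rdname accessors
#' @export
setGeneric("templateVolume", function(object) standardGeneric("templateVolume"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
setMethod("voxelSize", "TissueVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "RoiAtlas", function(object) object@voxelSize)
#' @rdname accessors
setMethod("gridOrigin", "TissueVolume", function(object) object@origin)
#' @rdname accessors
setMethod("gridOrigin", "RoiAtlas", function(object) object@origin)
#' @rdname accessors
setMethod("labelMap", "TissueVolume", function(object) object@labels)
#' @rdname accessors
setMethod("labelData", "TissueVolume", function(object) object@data)
#' @rdname accessors
setMethod("labelData", "RoiAtlas", function(object) object@data)
#' @rdname accessors
setMethod("roiNames", "RoiAtlas", function(object) object@roiNames)
#' @rdname accessors
setMethod("roiVolumes", "RoiAtlas", function(object) object@roiVolumes)
#' @rdname accessors
setMethod("shellRadii", "ShellModel", function(object) object@radii)
#' @rdname accessors
setMethod("shellConductivities", "ShellModel",
          function(object) object@conductivities)
#' @rdname accessors
setMethod("shellCenter", "ShellModel", function(object) object@center)
#' @rdname accessors
setMethod("electrodeNames", "ElectrodeMontage", function(object) object@names)
#' @rdname accessors
setMethod("electrodePositions", "ElectrodeMontage",
          function(object) object@positions)
#' @rdname accessors
setMethod("clusterMap", "ElectrodeMontage", function(object) object@clusters)
#' @rdname accessors
setMethod("gainMatrix", "LeadField", function(object) object@gain)
#' @rdname accessors
setMethod("sourcePositions", "LeadField",
          function(object) object@sourcePositions)
#' @rdname accessors
setMethod("sourceRoi", "LeadField", function(object) object@sourceRoi)
#' @rdname accessors
setMethod("electrodeNames", "LeadField",
          function(object) object@electrodeNames)
#' @rdname accessors
setMethod("erpData", "ErpAverage", function(object) object@data)
#' @rdname accessors
setMethod("samplingRate", "ErpAverage", function(object) object@samplingRate)
#' @rdname accessors
setMethod("timesMs", "ErpAverage", function(object)
  object@t0 + (seq_len(ncol(object@data)) - 1) * 1000 / object@samplingRate)
#' @rdname accessors
setMethod("inverseMapping", "EloretaOperator", function(object) object@mapping)
#' @rdname accessors
setMethod("sourceWeights", "EloretaOperator", function(object) object@weights)
#' @rdname accessors
setMethod("rmsTrace", "TemplateModel", function(object) object@rmsTrace)
#' @rdname accessors
setMethod("templateVolume", "TemplateModel", function(object) object@volume)
#' @rdname accessors
setMethod("isConverged", "TemplateModel", function(object) object@converged)

#' World coordinates of every voxel centre
#'
#' @param object a \linkS4class{TissueVolume} or \linkS4class{RoiAtlas}.
#' @return numeric matrix (n_voxels x 3) in array (column-major) order.
#' @export
voxelCoordinates <- function(object) {
  d <- dim(labelData(object))
  v <- voxelSize(object)
  o <- gridOrigin(object)
  i <- rep.int(seq_len(d[1]), d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  cbind(o[1] + (i - 1) * v, o[2] + (j - 1) * v, o[3] + (k - 1) * v)
}

setMethod("show", "TissueVolume", function(object) {
  d <- dim(object@data)
  cat("TissueVolume:", paste(d, collapse = " x "),
      sprintf("voxels @ %g mm\n", object@voxelSize))
  counts <- tabulate(match(as.integer(object@data), object@labels),
                     nbins = length(object@labels))
  names(counts) <- names(object@labels)
  cat("  labels:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
})

setMethod("show", "RoiAtlas", function(object) {
  cat("RoiAtlas:", length(object@roiNames), "ROIs on",
      paste(dim(object@data), collapse = " x "),
      sprintf("grid @ %g mm\n", object@voxelSize))
})

setMethod("show", "ShellModel", function(object) {
  cat("ShellModel: radii (mm)",
      paste(sprintf("%s=%.1f", names(object@radii), object@radii),
            collapse = ", "),
      sprintf("\n  order %d, fit residual %.2f mm\n",
              object@order, object@residual))
})

setMethod("show", "ElectrodeMontage", function(object) {
  cat("ElectrodeMontage:", length(object@names), "electrodes,",
      length(object@clusters), "clusters\n")
})

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@gain), "electrodes x",
      nrow(object@sourcePositions), "sources (uV per nA*m,",
      object@reference, "reference)\n")
})

setMethod("show", "ErpAverage", function(object) {
  tt <- timesMs(object)
  cat(sprintf("ErpAverage [%s/%s]: %d channels x %d samples, %g Hz, %g..%g ms\n",
              object@group, object@condition, nrow(object@data),
              ncol(object@data), object@samplingRate, min(tt), max(tt)))
})

setMethod("show", "EloretaOperator", function(object) {
  cat(sprintf("EloretaOperator: %d sources x %d electrodes, alpha %g, %d iterations (final change %.2e)\n",
              nrow(object@mapping) / 3, ncol(object@mapping), object@alpha,
              object@iterations, utils::tail(object@trace, 1)))
})

setMethod("show", "TemplateModel", function(object) {
  cat(sprintf("TemplateModel: %d inputs, %d iterations, converged = %s\n",
              length(object@transforms), object@nIterations,
              object@converged))
})
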