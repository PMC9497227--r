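# Persistence: NIfTI-1 label volumes with JSON label sidecars, ERP CSV +
# JSON sidecars, lead fields as a binary array container with a JSON
# header, and the cohort manifest.

.affine <- function(voxelSize, origin) {
  a <- diag(c(voxelSize, voxelSize, voxelSize, 1))
  a[1:3, 4] <- origin
  a
}

#' Write / read a tissue label volume as NIfTI-1 + JSON sidecar
#'
#' The sidecar (same path with extension \code{.labels.json}) maps label
#' integers to tissue names.
#'
#' @param volume a \linkS4class{TissueVolume}.
#' @param path output path ending in \code{.nii} (uncompressed NIfTI-1).
#' @return the path (write) or the \linkS4class{TissueVolume} (read).
#' @export
writeTissueVolume <- function(volume, path) {
  img <- RNifti::asNifti(labelData(volume))
  img <- RNifti::`sform<-`(img, structure(.affine(voxelSize(volume),
                                                  gridOrigin(volume)),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(as.list(labelMap(volume)), side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTissueVolume
#' @export
readTissueVolume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  labels <- unlist(jsonlite::read_json(side))
  aff <- RNifti::xform(img)
  arr <- array(as.integer(img), dim = dim(img))
  new("TissueVolume", data = arr, voxelSize = unname(aff[1, 1]),
      origin = unname(aff[1:3, 4]),
      labels = stats::setNames(as.integer(labels), names(labels)))
}

#' Write a CDR map or ROI atlas as NIfTI-1 on the atlas grid
#'
#' @param atlas a \linkS4class{RoiAtlas}.
#' @param path output path; the ROI name map goes to a \code{.labels.json}
#'   sidecar.
#' @param values optional per-source values and source grid (list with
#'   \code{positions} and the values); when given, a float volume with the
#'   values splatted at the source voxels is written instead of labels.
#' @export
writeAtlasVolume <- function(atlas, path, values = NULL) {
  arr <- labelData(atlas)
  if (!is.null(values)) {
    out <- array(0, dim = dim(arr))
    v <- voxelSize(atlas)
    idx <- round(sweep(values$positions, 2, gridOrigin(atlas)) / v) + 1
    lin <- (idx[, 3] - 1) * dim(arr)[1] * dim(arr)[2] +
      (idx[, 2] - 1) * dim(arr)[1] + idx[, 1]
    out[lin] <- values$amplitude
    arr <- out
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(.affine(voxelSize(atlas),
                                                  gridOrigin(atlas)),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(as.list(roiNames(atlas)), side, auto_unbox = TRUE)
  invisible(path)
}

#' Write / read an ERP average as CSV + JSON sidecar
#'
#' CSV rows are channels, columns samples; the sidecar records
#' \code{sampling_rate_hz, t0_ms, condition, group, reference}.
#'
#' @param erp an \linkS4class{ErpAverage}. @param path CSV path; sidecar
#'   at the same path with \code{.json} substituted.
#' @export
writeErpAverage <- function(erp, path) {
  m <- erpData(erp)
  rownames(m) <- erp@channels
  utils::write.csv(m, path, row.names = TRUE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(sampling_rate_hz = samplingRate(erp),
                            t0_ms = erp@t0, condition = erp@condition,
                            group = erp@group, reference = erp@reference),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeErpAverage
#' @export
readErpAverage <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  new("ErpAverage", data = unname(m), channels = rownames(m),
      samplingRate = meta$sampling_rate_hz, t0 = meta$t0_ms,
      condition = meta$condition, group = meta$group,
      reference = meta$reference)
}

#' Write / read a lead field as a binary array container + JSON header
#'
#' Gains are stored as little-endian doubles in column-major order; the
#' header records the electrode order, source grid, units and series
#' order.
#'
#' @param leadField a \linkS4class{LeadField}. @param path path of the
#'   binary file; the header lives alongside with \code{.json} appended.
#' @export
writeLeadField <- function(leadField, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(gainMatrix(leadField)), con, size = 8,
           endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_electrodes = nrow(gainMatrix(leadField)),
         n_sources = nrow(sourcePositions(leadField)),
         electrodes = electrodeNames(leadField),
         source_positions_mm = sourcePositions(leadField),
         source_roi = sourceRoi(leadField),
         units = "uV per nA*m", order = leadField@order,
         reference = leadField@reference),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLeadField
#' @export
readLeadField <- function(path) {
  h <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  gain <- readBin(con, "numeric", n = h$n_electrodes * 3 * h$n_sources,
                  size = 8, endian = "little")
  close(con)
  new("LeadField", gain = matrix(gain, nrow = h$n_electrodes),
      sourcePositions = matrix(h$source_positions_mm, ncol = 3),
      sourceRoi = as.integer(h$source_roi), electrodeNames = h$electrodes,
      order = as.integer(h$order), reference = h$reference)
}

#' Write a cohort manifest
#'
#' JSON listing of subjects, groups, any persisted file paths, and the
#' generating seed.
#'
#' @param cohort a cohort from \code{\link{makeCohort}}.
#' @param path JSON path. @param files optional named list subject ->
#'   file paths.
#' @export
writeCohortManifest <- function(cohort, path, files = NULL) {
  subjects <- lapply(cohort$subjects, function(s) {
    out <- list(id = s$id, group = s$group,
                shell_radii_mm = as.list(shellRadii(s$shell)))
    if (!is.null(files[[s$id]])) out$files <- files[[s$id]]
    out
  })
  jsonlite::write_json(list(seed = cohort$config$seed,
                            n_per_group = as.list(cohort$config$nPerGroup),
                            subjects = unname(subjects)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
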