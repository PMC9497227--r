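# Tissue conductivity assignment.

#' Default tissue conductivity table
#'
#' Reference conductivities (S/m) for the nine segmented head tissue
#' classes used in infant FEM head modelling: scalp 0.35, skull 0.0132,
#' CSF 1.79, white matter 0.2, gray matter 0.33, dura 0.33, muscles 0.35,
#' eyes 0.5, nasal cavity 0.0048.
#'
#' @return named numeric vector, S/m.
#' @export
defaultConductivities <- function() {
  c(scalp = 0.35, skull = 0.0132, csf = 1.79, white = 0.2, gray = 0.33,
    dura = 0.33, muscles = 0.35, eyes = 0.5, nasal_cavity = 0.0048)
}

#' Assign conductivities to a tissue label volume
#'
#' Maps every voxel's tissue label to its conductivity; background is 0.
#'
#' @param volume a \linkS4class{TissueVolume}.
#' @param table named numeric vector, tissue name to S/m; every
#'   non-background label in \code{volume} must be named.
#' @return numeric 3D array of conductivities (S/m) on the volume grid.
#' @export
assignConductivities <- function(volume, table = defaultConductivities()) {
  lm <- labelMap(volume)
  present <- names(lm)[lm %in% unique(as.integer(labelData(volume)))]
  present <- setdiff(present, "background")
  missing <- setdiff(present, names(table))
  if (length(missing))
    stop("no conductivity for label(s): ", paste(missing, collapse = ", "))
  lut <- numeric(max(lm) + 1L)
  for (nm in present) lut[lm[[nm]] + 1L] <- table[[nm]]
  out <- array(lut[as.integer(labelData(volume)) + 1L],
               dim = dim(labelData(volume)))
  out
}
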