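# eLORETA inverse operator, current-density reconstruction over the N290
# peak window, and per-ROI summarization.

#' Build the eLORETA inverse operator
#'
#' Iterates the eLORETA source weights: with sensor-space matrix
#' C = L W^-1 L' + alpha * mu * H (H the average-reference centering
#' operator, mu the mean sensor-space eigenvalue), each source's 3x3
#' weight is replaced by the symmetric square root of L_j' C^+ L_j until
#' the largest relative weight change falls below \code{tol}. The inverse
#' mapping is W^-1 L' C^+. With noiseless single-dipole data and small
#' alpha this operator has zero localization error.
#'
#' @param leadField an average-referenced \linkS4class{LeadField}.
#' @param alpha regularization, relative to the mean sensor-space
#'   eigenvalue; >= 0.
#' @param tol convergence tolerance on the max relative weight change.
#' @param maxIter iteration cap; non-convergence is an error carrying the
#'   convergence trace in the condition.
#' @return an \linkS4class{EloretaOperator}.
#' @export
buildEloretaOperator <- function(leadField, alpha = 0.05, tol = 1e-6,
                                 maxIter = 100L) {
  stopifnot(alpha >= 0)
  if (!identical(leadField@reference, "average"))
    stop("lead field must be average-referenced")
  res <- .eloretaCore(gainMatrix(leadField), alpha, tol, as.integer(maxIter))
  if (!res$converged) {
    cond <- structure(
      class = c("eloretaNonConvergence", "error", "condition"),
      list(message = sprintf(
             "eLORETA did not converge in %d iterations (last change %.3e)",
             res$iterations, utils::tail(res$trace, 1)),
           call = sys.call(), trace = res$trace))
    stop(cond)
  }
  new("EloretaOperator", mapping = res$mapping, weights = res$weights,
      alpha = alpha, trace = as.numeric(res$trace),
      iterations = as.integer(res$iterations), reference = "average")
}

#' Current density reconstruction over the peak window
#'
#' Applies the inverse operator to the 20 ms of data centred on the
#' detected N290 peak and reduces each source's three-component moment
#' time course to a single amplitude.
#'
#' @param operator an \linkS4class{EloretaOperator}.
#' @param erp an \linkS4class{ErpAverage} whose channels match the
#'   operator's lead field.
#' @param peak a one-row peak table (from \code{\link{detectN290}}) or a
#'   numeric N290 latency in ms.
#' @param windowMs full window length around the peak, ms.
#' @param summary \code{"mean"} (default) or \code{"max"} of the
#'   per-sample moment norms over the window.
#' @return list with \code{amplitude} (nA*m per source), \code{window}
#'   (ms), and \code{moments} (3 x sources x samples array).
#' @export
computeCdr <- function(operator, erp, peak, windowMs = 20,
                       summary = c("mean", "max")) {
  summary <- match.arg(summary)
  lat <- if (is.data.frame(peak)) peak$n290_latency[1] else as.numeric(peak)
  tt <- timesMs(erp)
  lo <- lat - windowMs / 2
  hi <- lat + windowMs / 2
  if (lo < min(tt) || hi > max(tt))
    stop("CDR window [", lo, ", ", hi, "] ms exceeds the sampled record")
  sel <- which(tt >= lo - 1e-9 & tt <= hi + 1e-9)
  x <- erpData(erp)[, sel, drop = FALSE]
  J <- inverseMapping(operator) %*% x   # (3 nS) x nT
  nS <- nrow(J) / 3L
  dim(J) <- c(3L, nS, ncol(x))
  norms <- sqrt(apply(J^2, c(2, 3), sum))
  if (is.null(dim(norms))) norms <- matrix(norms, nrow = nS)
  amp <- if (summary == "mean") rowMeans(norms) else
    apply(norms, 1, max)
  list(amplitude = amp, window = c(lo, hi), moments = J)
}

#' Summarize current density per ROI
#'
#' Per-ROI value = (sum of source amplitudes over the ROI) / (ROI volume
#' in mm^3), i.e. average current per mm^3. ROIs with no sources are
#' returned as NA (flagged missing, not zero).
#'
#' @param cdr result of \code{\link{computeCdr}} (or a numeric amplitude
#'   vector).
#' @param leadField the \linkS4class{LeadField} the operator was built
#'   from (carries the source-to-ROI map).
#' @param atlas the \linkS4class{RoiAtlas} the source grid came from.
#' @return data.frame with columns \code{roi}, \code{value}, \code{n_sources}.
#' @export
summarizeRoi <- function(cdr, leadField, atlas) {
  amp <- if (is.list(cdr)) cdr$amplitude else as.numeric(cdr)
  roi <- sourceRoi(leadField)
  if (length(amp) != length(roi))
    stop("amplitude length does not match the lead field source count")
  nm <- roiNames(atlas)
  vols <- roiVolumes(atlas)
  sums <- vapply(nm, function(code) sum(amp[roi == code]), numeric(1))
  counts <- vapply(nm, function(code) sum(roi == code), numeric(1))
  value <- ifelse(counts > 0, sums / vols[names(nm)], NA_real_)
  data.frame(roi = names(nm), value = as.numeric(value),
             n_sources = as.integer(counts), row.names = NULL)
}
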