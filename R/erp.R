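# ERP measurement layer: cluster averaging and the P1-anchored N290 peak
# detector with its 400 ms bound, 290 ms fallback and peak-to-peak
# amplitude.
#
# A "local extremum" is a sample at least as large (P1) or as small
# (N290) as every sample within +/- 3 samples and strictly so for at
# least one of them, with a full neighbourhood inside the search window;
# ties resolve to the earlier latency. The deterministic rule plus the
# fallback flag stands in for manual peak inspection.

#' Average an ERP over a posterior electrode cluster
#'
#' @param erp an \linkS4class{ErpAverage}.
#' @param montage the matching \linkS4class{ElectrodeMontage}.
#' @param clusterName one of the cluster names (\code{names(clusterMap(montage))})
#'   or \code{"all"} for the pointwise mean over all 12 clusters' distinct
#'   electrodes.
#' @return numeric vector, one sample per time point (uV).
#' @export
clusterAverage <- function(erp, montage, clusterName) {
  cl <- clusterMap(montage)
  if (identical(clusterName, "all")) {
    members <- unique(unlist(cl))
  } else {
    if (!clusterName %in% names(cl))
      stop("unknown cluster: ", clusterName)
    members <- cl[[clusterName]]
  }
  idx <- match(members, erp@channels)
  if (anyNA(idx))
    stop("cluster electrodes missing from the ERP: ",
         paste(members[is.na(idx)], collapse = ", "))
  colMeans(erpData(erp)[idx, , drop = FALSE])
}

# indices of strict local maxima over a full +/- 3 sample neighbourhood;
# samples too close to the window edge for a full neighbourhood never
# qualify (so monotone stretches produce no extremum)
.localMaxima <- function(x, halfWidth = 3L) {
  n <- length(x)
  if (n < 2L * halfWidth + 1L) return(integer(0))
  out <- logical(n)
  for (i in (halfWidth + 1L):(n - halfWidth)) {
    nb <- x[setdiff((i - halfWidth):(i + halfWidth), i)]
    # >= admits the twin samples of a peak centred between samples
    # (resolved to the earlier latency downstream); all-equal plateaus
    # are not extrema
    out[i] <- all(x[i] >= nb) && any(x[i] > nb)
  }
  which(out)
}

#' Detect the P1 peak
#'
#' Latency of the maximum positive local extremum inside the search
#' window; if no positive local extremum exists, the global window maximum
#' is taken and flagged.
#'
#' @param waveform numeric vector (uV). @param times matching latencies
#'   (ms). @param searchWindow length-2 ms window (default 80-200 ms).
#' @return list \code{latency}, \code{amplitude}, \code{fallback}.
#' @export
detectP1 <- function(waveform, times, searchWindow = c(80, 200)) {
  if (searchWindow[1] < min(times) || searchWindow[2] > max(times))
    stop("P1 search window outside the sampled range")
  sel <- which(times >= searchWindow[1] & times <= searchWindow[2])
  w <- waveform[sel]
  cand <- .localMaxima(w)
  cand <- cand[w[cand] > 0]
  if (length(cand)) {
    best <- cand[which.max(w[cand])]   # which.max takes the earliest tie
    list(latency = times[sel][best], amplitude = w[best], fallback = FALSE)
  } else {
    best <- which.max(w)
    warning("no positive local extremum in the P1 window; using the window maximum")
    list(latency = times[sel][best], amplitude = w[best], fallback = TRUE)
  }
}

#' Detect the N290 peak anchored at the P1
#'
#' Most negative local extremum strictly after the P1 latency and at or
#' before 400 ms. If no local extremum exists in that span the sample at
#' 290 ms is taken and \code{fallback_used} is set. The reported
#' \code{peak_to_peak} is the P1-to-N290 amplitude change.
#'
#' @param waveform numeric vector (uV). @param times latencies (ms).
#' @param p1 result of \code{\link{detectP1}} (or a numeric P1 latency,
#'   in which case the P1 amplitude is read off the waveform).
#' @param bound latest admissible N290 latency, ms.
#' @return one-row data.frame: \code{p1_latency, p1_amplitude,
#'   n290_latency, n290_amplitude, peak_to_peak, fallback_used}.
#' @export
detectN290 <- function(waveform, times, p1, bound = 400) {
  if (max(times) < bound)
    stop("waveform ends before ", bound, " ms post-stimulus")
  if (is.numeric(p1))
    p1 <- list(latency = p1,
               amplitude = waveform[which.min(abs(times - p1))])
  if (p1$latency >= bound) stop("P1 latency must precede ", bound, " ms")
  sel <- which(times > p1$latency & times <= bound)
  w <- waveform[sel]
  cand <- .localMaxima(-w)
  if (length(cand)) {
    best <- cand[which.max(-w[cand])]
    lat <- times[sel][best]
    amp <- w[best]
    fallback <- FALSE
  } else {
    i290 <- which.min(abs(times - 290))
    lat <- times[i290]
    amp <- waveform[i290]
    fallback <- TRUE
  }
  data.frame(p1_latency = p1$latency, p1_amplitude = p1$amplitude,
             n290_latency = lat, n290_amplitude = amp,
             peak_to_peak = p1$amplitude - amp, fallback_used = fallback)
}

#' Peak table for a cohort
#'
#' Runs the P1-anchored N290 detector per subject and condition on the
#' mean over all 12 posterior clusters (with per-cluster values available
#' as diagnostics via \code{perCluster}).
#'
#' @param cohort a cohort from \code{\link{makeCohort}}.
#' @param perCluster also emit one row per individual cluster.
#' @return data.frame: subject, group, condition, cluster, p1_latency,
#'   p1_amplitude, n290_latency, n290_amplitude, peak_to_peak,
#'   fallback_used.
#' @export
peakTable <- function(cohort, perCluster = FALSE) {
  rows <- list()
  for (subj in cohort$subjects) {
    clusters <- if (perCluster)
      c("all", names(clusterMap(subj$montage))) else "all"
    for (cnd in names(subj$erp)) {
      erp <- subj$erp[[cnd]]
      tt <- timesMs(erp)
      for (cl in clusters) {
        w <- clusterAverage(erp, subj$montage, cl)
        pk <- detectN290(w, tt, detectP1(w, tt))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(subject = subj$id, group = subj$group,
                           condition = cnd, cluster = cl), pk)
      }
    }
  }
  do.call(rbind, rows)
}
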