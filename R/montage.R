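# Electrode montage template and fiducial-anchored scalp placement.
#
# The montage is a 64-channel subset of a 128-electrode geodesic layout:
# the 26 numbered electrodes referenced by the 12 posterior measurement
# clusters, placed at hand-set posterior-inferior directions with exact
# left/right mirror symmetry, plus unnamed filler electrodes spread over
# the upper head, plus the three fiducials.

# left-hemisphere cluster electrodes: number, azimuth (deg from nasion,
# positive toward the left), elevation (deg above the horizontal plane)
.clusterElectrodeAngles <- function() {
  left <- rbind(
    `46` = c(115, -10), `50` = c(125, -15), `51` = c(125,   2),
    `56` = c(135, -25), `57` = c(140, -12), `58` = c(140,   3),
    `59` = c(150,   8), `63` = c(150, -22), `64` = c(155, -10),
    `65` = c(160,   0), `66` = c(165,  10), `68` = c(165, -18),
    `69` = c(172,  -8)
  )
  pairs <- c(`46` = 102, `50` = 101, `51` = 97, `56` = 107, `57` = 100,
             `58` = 96, `59` = 91, `63` = 99, `64` = 95, `65` = 90,
             `66` = 84, `68` = 94, `69` = 89)
  right <- left
  right[, 1] <- -right[, 1]
  rownames(right) <- as.character(pairs[rownames(left)])
  rbind(left, right)
}

#' The 12 posterior electrode clusters
#'
#' Parietal-occipital (PO7/PO8/PO9/PO10), parietal (P7/P8/P9/P10) and
#' temporal-parietal (TP7/TP8/TP9/TP10) clusters over which the N290 is
#' measured, each listing its member electrodes in the 128-channel
#' geodesic numbering.
#'
#' @return named list of character vectors of electrode names.
#' @export
posteriorClusters <- function() {
  num <- list(
    PO7 = c(59, 65, 66),      PO8 = c(84, 90, 91),
    PO9 = c(64, 65, 68, 69),  PO10 = c(89, 90, 94, 95),
    P7  = c(51, 58, 59),      P8  = c(91, 96, 97),
    P9  = c(57, 58, 63, 64),  P10 = c(95, 96, 99, 100),
    TP7 = c(46, 50, 51),      TP8 = c(97, 101, 102),
    TP9 = c(50, 56, 57),      TP10 = c(100, 101, 107)
  )
  lapply(num, function(v) paste0("E", v))
}

.sph2unit <- function(azDeg, elDeg) {
  az <- azDeg * pi / 180
  el <- elDeg * pi / 180
  # azimuth measured from +y (nasion) toward -x (left ear)
  cbind(x = -cos(el) * sin(az), y = cos(el) * cos(az), z = sin(el))
}

#' Build the unit-sphere montage template
#'
#' @param nFiller number of filler electrodes distributed over the upper
#'   head (elevation above 15 degrees) on a Fibonacci lattice.
#' @return data.frame with columns \code{name, x, y, z}; unit vectors.
#'   Rows \code{nasion}, \code{lpa}, \code{rpa} are the fiducials.
#' @export
makeMontageTemplate <- function(nFiller = 35L) {
  ang <- .clusterElectrodeAngles()
  cl <- .sph2unit(ang[, 1], ang[, 2])
  clNames <- paste0("E", rownames(ang))
  # Fibonacci lattice restricted to the upper cap
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(nFiller)
  z <- sin(15 * pi / 180) + (i - 0.5) / nFiller * (1 - sin(15 * pi / 180))
  th <- 2 * pi * i / golden
  fl <- cbind(x = sqrt(1 - z^2) * cos(th), y = sqrt(1 - z^2) * sin(th),
              z = z)
  flNames <- sprintf("F%02d", i)
  fid <- rbind(nasion = c(0, cos(15 * pi / 180), -sin(15 * pi / 180)),
               lpa = c(-cos(20 * pi / 180), 0, -sin(20 * pi / 180)),
               rpa = c(cos(20 * pi / 180), 0, -sin(20 * pi / 180)))
  out <- data.frame(name = c(clNames, flNames, rownames(fid)),
                    rbind(cl, fl, fid), row.names = NULL)
  names(out) <- c("name", "x", "y", "z")
  out
}

#' Read / write a montage template file
#'
#' Plain-text format: one electrode per line, \code{name x y z}, unit
#' sphere directions; fiducials are the rows named \code{nasion},
#' \code{lpa}, \code{rpa}.
#'
#' @param path file path.
#' @param template data.frame as from \code{\link{makeMontageTemplate}}.
#' @return \code{readMontageTemplate}: the template data.frame.
#' @export
readMontageTemplate <- function(path) {
  out <- utils::read.table(path, header = FALSE,
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  nrm <- sqrt(out$x^2 + out$y^2 + out$z^2)
  if (any(abs(nrm - 1) > 1e-3))
    stop("montage template directions must be unit vectors")
  out
}

#' @rdname readMontageTemplate
#' @export
writeMontageTemplate <- function(template, path) {
  utils::write.table(template, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Default montage template shipped with the package
#' @return data.frame, see \code{\link{makeMontageTemplate}}.
#' @export
defaultMontageTemplate <- function() {
  readMontageTemplate(system.file("extdata", "montage_template.txt",
                                  package = "erpsource", mustWork = TRUE))
}

#' Place template electrodes on a head model's scalp
#'
#' Each electrode is the radial projection of its template unit direction
#' onto the scalp shell radius. The fiducial directions define the frame
#' orientation: the template frame (x along the preauricular axis, y
#' toward the nasion) is rotated onto the head model's world axes before
#' projection.
#'
#' @param shellModel a \linkS4class{ShellModel}.
#' @param template montage template data.frame
#'   (\code{\link{defaultMontageTemplate}}).
#' @return an \linkS4class{ElectrodeMontage}.
#' @export
placeElectrodes <- function(shellModel, template = defaultMontageTemplate()) {
  fidNames <- c("nasion", "lpa", "rpa")
  if (!all(fidNames %in% template$name))
    stop("montage template must include fiducials nasion, lpa, rpa")
  clusters <- posteriorClusters()
  needed <- unique(unlist(clusters))
  missing <- setdiff(needed, template$name)
  if (length(missing))
    stop("montage template is missing clustered electrode(s): ",
         paste(missing, collapse = ", "))
  m <- as.matrix(template[, c("x", "y", "z")])
  rownames(m) <- template$name
  fid <- m[fidNames, , drop = FALSE]
  ex <- fid["rpa", ] - fid["lpa", ]
  ex <- ex / sqrt(sum(ex^2))
  ey <- fid["nasion", ] - (fid["rpa", ] + fid["lpa", ]) / 2
  ey <- ey - sum(ey * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  # rotation taking the template's fiducial frame onto the world axes
  rot <- t(cbind(ex, ey, ez))
  elecSel <- !template$name %in% fidNames
  dirs <- m[elecSel, , drop = FALSE] %*% t(rot)
  dirs <- dirs / sqrt(rowSums(dirs^2))   # exact radial projection
  rScalp <- shellRadii(shellModel)[["scalp"]]
  ctr <- shellCenter(shellModel)
  pos <- sweep(dirs * rScalp, 2, ctr, "+")
  fidPos <- sweep(fid %*% t(rot) * rScalp, 2, ctr, "+")
  new("ElectrodeMontage", names = template$name[elecSel],
      positions = unname(pos), clusters = clusters,
      fiducials = unname(fidPos))
}
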