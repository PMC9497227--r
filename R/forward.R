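# Analytic four-shell forward model.
#
# The potential of a current dipole inside a piecewise-homogeneous
# concentric-shell conductor is expanded in Legendre series; per degree n
# the radial part solves a small linear boundary-value system (continuity
# of potential and of radial current at each interface, zero radial
# current at the scalp surface). Radii are normalised by the scalp radius
# so the per-degree solve stays well conditioned at high order.

# per-degree radial gains at the outer surface, for degrees 1..order;
# equals (2n+1)/n when all four conductivities are equal. Each shell uses
# basis functions scaled by its own outer radius ((x/x_k)^n, (x_k/x)^(n+1))
# so the per-degree linear system stays well conditioned at high order.
.shellGains <- function(shellModel, order = shellModel@order) {
  x <- shellRadii(shellModel) / shellRadii(shellModel)[["scalp"]]
  s <- unname(shellConductivities(shellModel))
  g <- numeric(order)
  # unknown columns: A1, A2, B2, A3, B3, A4, B4 (B1 replaced by primary)
  colA <- c(1, 2, 4, 6)
  colB <- c(NA, 3, 5, 7)
  for (n in seq_len(order)) {
    f <- function(xx, xo) (xx / xo)^n                 # growing basis
    fp <- function(xx, xo) n * (xx / xo)^n / xx       # its derivative
    h <- function(xx, xo) (xo / xx)^(n + 1)           # decaying basis
    hp <- function(xx, xo) -(n + 1) * (xo / xx)^(n + 1) / xx
    A <- matrix(0, 7, 7)
    b <- numeric(7)
    row <- 1
    for (k in 1:3) {   # interface between shell k and k+1 at radius x[k]
      xi <- x[[k]]
      A[row, colA[k]] <- f(xi, x[[k]])
      if (!is.na(colB[k])) A[row, colB[k]] <- h(xi, x[[k]])
      A[row, colA[k + 1]] <- -f(xi, x[[k + 1]])
      A[row, colB[k + 1]] <- -h(xi, x[[k + 1]])
      b[row] <- if (k == 1) -xi^(-(n + 1)) else 0
      row <- row + 1
      A[row, colA[k]] <- s[k] * fp(xi, x[[k]])
      if (!is.na(colB[k])) A[row, colB[k]] <- s[k] * hp(xi, x[[k]])
      A[row, colA[k + 1]] <- -s[k + 1] * fp(xi, x[[k + 1]])
      A[row, colB[k + 1]] <- -s[k + 1] * hp(xi, x[[k + 1]])
      b[row] <- s[1] * (n + 1) * xi^(-(n + 2)) * (if (k == 1) 1 else 0)
      row <- row + 1
    }
    # insulated outer boundary at x = 1 (x4 = 1 so bases are unscaled)
    A[7, 6] <- n
    A[7, 7] <- -(n + 1)
    sol <- solve(A, b)
    g[n] <- sol[6] + sol[7]
  }
  g
}

#' Compute the four-shell lead field
#'
#' Gain matrix of unit dipoles at the source positions, evaluated with the
#' Legendre-series solution of the concentric-shell conductor truncated at
#' the model's series order, then average-referenced. Units are uV per
#' nA*m with geometry in mm and conductivity in S/m.
#'
#' @param shellModel a \linkS4class{ShellModel}.
#' @param montage an \linkS4class{ElectrodeMontage} on this model's scalp.
#' @param sources numeric matrix (n x 3) of world-mm source positions
#'   strictly inside the brain shell, or a source grid list from
#'   \code{\link{sourceGridFromAtlas}}.
#' @return a \linkS4class{LeadField}.
#' @export
computeLeadField <- function(shellModel, montage, sources) {
  roi <- NULL
  if (is.list(sources) && !is.matrix(sources)) {
    roi <- as.integer(sources$roi)
    sources <- sources$positions
  }
  sources <- as.matrix(sources)
  if (is.null(roi)) roi <- integer(nrow(sources))
  ctr <- shellCenter(shellModel)
  radii <- shellRadii(shellModel)
  src <- sweep(sources, 2, ctr)
  rs <- sqrt(rowSums(src^2))
  if (any(rs >= radii[["brain"]]))
    stop(sum(rs >= radii[["brain"]]),
         " source(s) lie outside the brain shell (r1 = ",
         radii[["brain"]], " mm)")
  elec <- sweep(electrodePositions(montage), 2, ctr)
  er <- sqrt(rowSums(elec^2))
  if (any(abs(er - radii[["scalp"]]) > 0.01 * radii[["scalp"]]))
    stop("electrodes are not on the scalp shell")
  elec <- elec * (radii[["scalp"]] / er)  # exact radial projection
  g <- .shellGains(shellModel)
  # truncation sanity: per-degree terms must decay for the deepest source
  tmax <- max(rs) / radii[["scalp"]]
  n <- length(g)
  tailTerm <- abs(g[n]) * tmax^(n - 1) * n
  headTerm <- max(abs(g[1:5]) * (1:5))
  if (!is.finite(tailTerm) || tailTerm > 1e-3 * headTerm)
    stop("Legendre series does not decay at order ", n,
         " for the deepest source; increase the order or shrink the grid")
  gain <- .leadfieldKernel(elec, src,
                           g, radii[["scalp"]],
                           shellConductivities(shellModel)[["brain"]])
  gain <- sweep(gain, 2, colMeans(gain))  # average reference
  new("LeadField", gain = gain, sourcePositions = sources,
      sourceRoi = roi, electrodeNames = electrodeNames(montage),
      order = shellModel@order, reference = "average")
}

#' Closed-form dipole potential in a homogeneous sphere
#'
#' Surface potential of a current dipole inside a homogeneous conducting
#' sphere with an insulating exterior, in the classical closed form
#' (image-free solution via the monopole generating function). Serves as
#' the independent oracle for the equal-conductivity limit of the
#' four-shell series.
#'
#' @param elecPos numeric matrix (n x 3), electrode positions (mm) on the
#'   sphere surface.
#' @param srcPos numeric length-3, dipole position (mm).
#' @param moment numeric length-3, dipole moment (nA*m).
#' @param radius sphere radius (mm).
#' @param center sphere centre (mm).
#' @param sigma conductivity (S/m).
#' @return potentials in uV (unreferenced).
#' @export
singleSphereDipolePotential <- function(elecPos, srcPos, moment,
                                        radius, center = c(0, 0, 0),
                                        sigma = 0.33) {
  elecPos <- as.matrix(elecPos)
  re <- sweep(elecPos, 2, center)
  r0 <- as.numeric(srcPos - center)
  out <- numeric(nrow(re))
  for (i in seq_len(nrow(re))) {
    e <- re[i, ]
    dvec <- e - r0
    d <- sqrt(sum(dvec^2))
    Fden <- radius^2 - sum(r0 * e) + radius * d
    grad <- 2 * dvec / d^3 + (e / radius + dvec / d) / Fden
    out[i] <- sum(moment * grad)
  }
  1000 / (4 * pi * sigma) * out
}
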