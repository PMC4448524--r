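#' @include io.R
NULL

#' Mass-weighted center of mass
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param masses n masses (amu), strictly positive. Default: unit masses.
#' @return Numeric 3-vector, Angstrom.
#' @examples
#' centerOfMass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3))  # (3, 0, 0)
#' @export
centerOfMass <- function(coords, masses = rep(1, nrow(coords))) {
  coords <- rbind(coords)
  if (nrow(coords) < 1L) stop("empty selection")
  if (length(masses) != nrow(coords) || any(masses <= 0))
    stop("masses must be positive, one per atom")
  as.numeric(colSums(coords * masses) / sum(masses))
}

#' Minimum-image distance in a periodic cubic box
#'
#' @param a,b 3-vectors, Angstrom.
#' @param boxEdge cubic box edge, Angstrom, > 0.
#' @return Distance to the nearest periodic image of \code{b}; at most
#'   \code{boxEdge * sqrt(3) / 2}.
#' @examples
#' pbcDistance(c(5, 5, 5), c(95, 5, 5), 100)  # 10
#' @export
pbcDistance <- function(a, b, boxEdge) {
  if (boxEdge <= 0) stop("boxEdge must be positive")
  d <- a - b
  d <- d - boxEdge * round(d / boxEdge)
  sqrt(sum(d^2))
}

#' Gyration diameter (twice the radius of gyration)
#'
#' The expected center-of-mass separation of a maximally compact dimer of
#' two identical globular molecules.
#'
#' @inheritParams centerOfMass
#' @return 2 x mass-weighted radius of gyration about the center of mass,
#'   Angstrom.
#' @examples
#' gyrationDiameter(rbind(c(-1, 0, 0), c(1, 0, 0)))  # 2
#' @export
gyrationDiameter <- function(coords, masses = rep(1, nrow(coords))) {
  coords <- rbind(coords)
  if (nrow(coords) < 1L) stop("empty selection")
  com <- centerOfMass(coords, masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  2 * sqrt(sum(masses * d2) / sum(masses))
}

## Kabsch: optimal rotation taking centered P onto centered Q.
.kabsch <- function(P, Q) {
  H <- crossprod(P, Q)                     # 3x3
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)      # R such that Q ~ P %*% t(R)
}

#' Orientation angle between two copies of the same molecule
#'
#' Both coordinate sets are centered on their centers of mass, the optimal
#' superposition rotation is computed, and the rotation angle
#' \eqn{\theta = \arccos((\mathrm{tr}\,R - 1)/2)} is returned. 0 degrees for
#' identically oriented copies; 180 degrees for a perfect two-fold (C2)
#' symmetric dimer.
#'
#' @param coordsRef,coordsOther n x 3 matrices with 1:1 atom correspondence.
#' @param masses optional masses for the COM centering (default unit).
#' @return Angle in degrees, in [0, 180].
#' @export
orientationAngle <- function(coordsRef, coordsOther,
                             masses = rep(1, nrow(coordsRef))) {
  if (nrow(coordsRef) != nrow(coordsOther))
    stop("coordinate sets must have equal atom counts")
  if (nrow(coordsRef) < 3L)
    stop("orientation angle needs >= 3 atoms")
  P <- sweep(coordsRef, 2, centerOfMass(coordsRef, masses))
  Q <- sweep(coordsOther, 2, centerOfMass(coordsOther, masses))
  sv <- svd(crossprod(P, Q))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30))
    stop("degenerate (collinear) coordinates: orientation angle undefined")
  R <- .kabsch(P, Q)
  cosang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Molecular dipole moment from point charges
#'
#' \eqn{\mu = \sum_i q_i (r_i - r_{COM})} converted to Debye with
#' 1 e Angstrom = 4.80320 D. For a net-neutral charge set the result is
#' independent of the reference point; a warning is issued when the net
#' charge exceeds 0.01 e (origin dependence) and when all charges are zero
#' (e.g. a topology read from plain PDB).
#'
#' @param coords n x 3 coordinates, Angstrom.
#' @param charges n partial charges, elementary-charge units.
#' @param masses masses for the COM reference point (default unit).
#' @return Numeric 3-vector in Debye.
#' @export
dipoleMoment <- function(coords, charges, masses = rep(1, nrow(coords))) {
  coords <- rbind(coords)
  if (nrow(coords) < 1L) stop("empty selection")
  if (all(charges == 0)) {
    warning("all charges are zero; dipole moment is a zero vector ",
            "(plain PDB input carries no charges)")
    return(c(0, 0, 0))
  }
  if (abs(sum(charges)) > 0.01)
    warning(sprintf(
      "net charge %.3f e > 0.01 e: dipole moment depends on the reference point",
      sum(charges)))
  com <- centerOfMass(coords, masses)
  as.numeric(colSums(sweep(coords, 2, com) * charges)) * .const$eA_to_debye
}

#' Angle between two vectors
#'
#' @param u,v nonzero 3-vectors.
#' @return Angle in degrees, in [0, 180].
#' @export
vectorAngle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Root-mean-square Brownian exploration length
#'
#' \eqn{\sqrt{6 D t}} expressed in Angstrom: the RMS displacement of a 3D
#' Brownian particle with diffusion coefficient D after time t.
#'
#' @param D diffusion coefficient, m^2/s, >= 0.
#' @param t time, s, >= 0.
#' @return Length in Angstrom.
#' @examples
#' brownianLength(2e-11, 1e-6)  # ~110 A per microsecond
#' brownianLength(5e-11, 1e-6)  # ~173 A
#' @export
brownianLength <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("D and t must be >= 0")
  sqrt(6 * D * t) * 1e10
}

#' Molar concentration of n copies in a cubic box
#'
#' @param nCopies number of solute copies, >= 1.
#' @param boxEdge cubic box edge, Angstrom, > 0.
#' @return Concentration in mM.
#' @examples
#' boxConcentration(3, 100)  # ~4.98 mM
#' @export
boxConcentration <- function(nCopies, boxEdge) {
  if (any(nCopies < 1)) stop("nCopies must be >= 1")
  if (any(boxEdge <= 0)) stop("boxEdge must be positive")
  volumeL <- (boxEdge * 1e-9)^3            # A^3 -> dm^3 (= L): 1 A = 1e-9 dm
  nCopies / (.const$N_A * volumeL) * 1e3   # mol/L -> mM
}

#' Per-frame center-of-mass series of one chain
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param chain chain id.
#' @return frames x 3 matrix of COM positions (Angstrom, as stored — wrapped
#'   if the trajectory is wrapped; see \code{\link{unwrapSeries}}).
#' @export
comSeries <- function(trajectory, chain) {
  idx <- chainAtomIndices(topology(trajectory), chain)
  m <- atoms(trajectory)$mass[idx]
  co <- coords(trajectory)
  t(vapply(seq_len(nFrames(trajectory)), function(f)
    centerOfMass(matrix(co[f, idx, ], ncol = 3), m), numeric(3)))
}

#' Remove periodic-boundary jumps from a position series
#'
#' Detects frame-to-frame displacements larger than half the box edge and
#' shifts subsequent frames by the corresponding box vector, producing a
#' continuous (unwrapped) series suitable for mean-squared-displacement
#' analysis.
#'
#' @param series frames x 3 matrix of positions, Angstrom.
#' @param boxEdge cubic box edge, Angstrom.
#' @return frames x 3 matrix, unwrapped.
#' @export
unwrapSeries <- function(series, boxEdge) {
  if (is.null(boxEdge)) return(series)
  d <- diff(series)
  d <- d - boxEdge * round(d / boxEdge)
  rbind(series[1, , drop = FALSE],
        sweep(apply(d, 2, cumsum), 2, series[1, ], "+"))
}

## minimum-image translation moving pointB next to pointA
.minImageShift <- function(pointA, pointB, boxEdge) {
  if (is.null(boxEdge)) return(c(0, 0, 0))
  boxEdge * round((pointA - pointB) / boxEdge)
}

#' Per-frame pair metrics for one chain pair
#'
#' Computes, for every frame, the center-of-mass distance (minimum image
#' when the trajectory carries a box), the optimal-superposition orientation
#' angle over heavy atoms, the angle between the two chains' dipole moments,
#' and the heavy-atom contact count at the given cutoff. Intra-chain
#' geometry uses the stored (whole-molecule) coordinates; only inter-chain
#' separations are imaged.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param pair character(2) chain ids.
#' @param cutoff contact cutoff, Angstrom (default 4).
#' @param metrics subset of \code{c("distance", "orientation", "dipole",
#'   "contacts")} to compute (the rest are NA); trimming the set speeds up
#'   long trajectories.
#' @return A \linkS4class{PairSeries}.
#' @export
computePairSeries <- function(trajectory, pair,
                              cutoff = 4,
                              metrics = c("distance", "orientation",
                                          "dipole", "contacts")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  topo <- topology(trajectory)
  a <- atoms(trajectory)
  iA <- chainAtomIndices(topo, pair[1]); iB <- chainAtomIndices(topo, pair[2])
  hA <- chainAtomIndices(topo, pair[1], heavyOnly = TRUE)
  hB <- chainAtomIndices(topo, pair[2], heavyOnly = TRUE)
  L <- boxEdge(trajectory)
  nf <- nFrames(trajectory)
  co <- coords(trajectory)

  doOrient <- "orientation" %in% metrics
  if (doOrient && length(hA) != length(hB)) {
    warning("chains have different heavy-atom counts; orientation angle ",
            "skipped (needs 1:1 correspondence)")
    doOrient <- FALSE
  }
  doDipole <- "dipole" %in% metrics
  if (doDipole &&
      (all(a$charge[iA] == 0) || all(a$charge[iB] == 0))) {
    warning("chain(s) carry zero charges; dipole angles not computed")
    doDipole <- FALSE
  }

  out <- data.frame(time_ns = frameTimes(trajectory),
                    com_distance_A = NA_real_, orientation_deg = NA_real_,
                    dipole_angle_deg = NA_real_, n_contacts = NA_integer_)
  for (f in seq_len(nf)) {
    xA <- matrix(co[f, iA, ], ncol = 3); xB <- matrix(co[f, iB, ], ncol = 3)
    comA <- centerOfMass(xA, a$mass[iA]); comB <- centerOfMass(xB, a$mass[iB])
    if ("distance" %in% metrics)
      out$com_distance_A[f] <- if (is.null(L)) sqrt(sum((comA - comB)^2))
                               else pbcDistance(comA, comB, L)
    if (doOrient)
      out$orientation_deg[f] <- orientationAngle(
        matrix(co[f, hA, ], ncol = 3), matrix(co[f, hB, ], ncol = 3),
        masses = a$mass[hA])
    if (doDipole) {
      muA <- suppressWarnings(dipoleMoment(xA, a$charge[iA], a$mass[iA]))
      muB <- suppressWarnings(dipoleMoment(xB, a$charge[iB], a$mass[iB]))
      if (sum(muA^2) > 0 && sum(muB^2) > 0)
        out$dipole_angle_deg[f] <- vectorAngle(muA, muB)
    }
    if ("contacts" %in% metrics) {
      shift <- .minImageShift(comA, comB, L)
      out$n_contacts[f] <- .contactCount(
        matrix(co[f, hA, ], ncol = 3),
        sweep(matrix(co[f, hB, ], ncol = 3), 2, shift, "+"),
        cutoff)$count
    }
  }
  new("PairSeries", chainPair = as.character(pair), series = out)
}
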