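#' @import methods
NULL

## ---------------------------------------------------------------------------
## Topology
## ---------------------------------------------------------------------------

#' Topology: chains, residues and atoms of a molecular system
#'
#' A \code{Topology} holds the static description of a system: one row per
#' atom with chain identifier, 1-based residue index (PDB numbering preserved
#' verbatim), residue and atom names, element symbol, heavy-atom flag, mass
#' (amu) and partial charge (elementary-charge units; zero when the source
#' format carries none).
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{elesy}, \code{heavy}, \code{mass},
#'   \code{charge}, one row per atom in file order.
#' @slot chains character vector of chain identifiers in first-appearance
#'   order.
#'
#' @section Validity:
#' \itemize{
#'   \item at least one chain, at least one atom;
#'   \item \code{(chain, resno, elety)} unique;
#'   \item \code{heavy} is \code{TRUE} exactly when the element is not
#'     hydrogen;
#'   \item all masses strictly positive.
#' }
#' @name Topology-class
#' @aliases Topology-class
#' @exportClass Topology
setClass("Topology",
         representation(atoms = "data.frame", chains = "character"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "elesy", "heavy",
            "mass", "charge")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("topology must contain at least one atom")
  if (length(object@chains) < 1L) return("topology must contain >= 1 chain")
  if (!setequal(unique(a$chain), object@chains))
    return("chains slot must list exactly the chain ids present in atoms")
  key <- paste(a$chain, a$resno, a$elety, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate atom key (chain, residue index, atom name)")
  if (!all(a$heavy == (toupper(a$elesy) != "H")))
    return("heavy flag inconsistent with element symbol")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("all atom masses must be positive")
  if (any(!is.finite(a$charge))) return("charges must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## Trajectory
## ---------------------------------------------------------------------------

#' Trajectory: coordinates over frames for a fixed Topology
#'
#' Coordinates are stored as a frames x atoms x 3 array in Angstrom. The box,
#' when present, is cubic and described by a single edge length. Frame times
#' are in nanoseconds and strictly increasing. A single-frame
#' \code{Trajectory} doubles as a structure (snapshot).
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric array, frames x atoms x 3, Angstrom, all finite.
#' @slot boxEdge numeric of length 0 (no box) or 1 (cubic edge, Angstrom > 0).
#' @slot frameTimes numeric, ns, strictly increasing, one per frame.
#' @name Trajectory-class
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
         representation(topology = "Topology", coords = "array",
                        boxEdge = "numeric", frameTimes = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return(sprintf("coords have %d atom rows but topology has %d atoms",
                   d[2], nrow(object@topology@atoms)))
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@boxEdge) > 1L)
    return("boxEdge must have length 0 or 1 (cubic box)")
  if (length(object@boxEdge) == 1L &&
      (!is.finite(object@boxEdge) || object@boxEdge <= 0))
    return("boxEdge must be positive")
  if (length(object@frameTimes) != d[1])
    return("frameTimes must have one entry per frame")
  if (d[1] > 1L && any(diff(object@frameTimes) <= 0))
    return("frameTimes must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## PairSeries
## ---------------------------------------------------------------------------

#' PairSeries: per-frame metrics for one chain pair
#'
#' Time series of center-of-mass distance (minimum image when a box is
#' present), optimal-superposition orientation angle, inter-dipole angle and
#' heavy-atom contact count for one pair of chains.
#'
#' @slot chainPair character(2), the two chain ids.
#' @slot series data.frame with columns \code{time_ns},
#'   \code{com_distance_A}, \code{orientation_deg}, \code{dipole_angle_deg},
#'   \code{n_contacts}. Angle columns may be \code{NA} when not computed
#'   (e.g. dipole angles on a charge-free topology).
#' @name PairSeries-class
#' @aliases PairSeries-class
#' @exportClass PairSeries
setClass("PairSeries",
         representation(chainPair = "character", series = "data.frame"))

setValidity("PairSeries", function(object) {
  if (length(object@chainPair) != 2L) return("chainPair must have length 2")
  s <- object@series
  need <- c("time_ns", "com_distance_A", "orientation_deg",
            "dipole_angle_deg", "n_contacts")
  if (!all(need %in% names(s)))
    return(paste("series must have columns:", paste(need, collapse = ", ")))
  ang <- c(s$orientation_deg, s$dipole_angle_deg)
  ang <- ang[!is.na(ang)]
  if (length(ang) && (any(ang < -1e-9) || any(ang > 180 + 1e-9)))
    return("angles must lie in [0, 180] degrees")
  nc <- s$n_contacts[!is.na(s$n_contacts)]
  if (length(nc) && any(nc < 0)) return("contact counts must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## DiffusionEstimate
## ---------------------------------------------------------------------------

#' DiffusionEstimate: translational diffusion coefficient from MSD
#'
#' @slot D numeric, translational diffusion coefficient, m^2/s, >= 0.
#' @slot fitWindow numeric(2), lag-time window of the linear fit, ns.
#' @slot fitQuality numeric in [0, 1], R^2 of the MSD-vs-lag linear fit.
#' @slot msd data.frame with columns \code{lag_ns}, \code{msd_A2}
#'   (the full averaged MSD curve, for inspection).
#' @name DiffusionEstimate-class
#' @aliases DiffusionEstimate-class
#' @exportClass DiffusionEstimate
setClass("DiffusionEstimate",
         representation(D = "numeric", fitWindow = "numeric",
                        fitQuality = "numeric", msd = "data.frame"))

setValidity("DiffusionEstimate", function(object) {
  if (length(object@D) != 1L || !is.finite(object@D) || object@D < 0)
    return("D must be a single non-negative number")
  if (length(object@fitWindow) != 2L) return("fitWindow must be (t_min, t_max)")
  if (object@fitQuality < -1e-9 || object@fitQuality > 1 + 1e-9)
    return("fitQuality must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## DipolePairState / BarrierSpec
## ---------------------------------------------------------------------------

#' DipolePairState: geometry of two interacting molecular dipoles
#'
#' Scalar description of a dipole pair: magnitudes in Debye, a single
#' inter-dipole angle in degrees, separation in Angstrom, and the relative
#' dielectric constant of the medium (78 for bulk water).
#'
#' @slot muA,muB numeric, dipole magnitudes, Debye, > 0.
#' @slot theta numeric, inter-dipole angle, degrees in [0, 180].
#' @slot r numeric, dipole-dipole separation, Angstrom, > 0.
#' @slot dielectric numeric, relative dielectric constant, > 0.
#' @name DipolePairState-class
#' @aliases DipolePairState-class
#' @exportClass DipolePairState
setClass("DipolePairState",
         representation(muA = "numeric", muB = "numeric", theta = "numeric",
                        r = "numeric", dielectric = "numeric"))

setValidity("DipolePairState", function(object) {
  if (any(object@muA <= 0) || any(object@muB <= 0))
    return("dipole magnitudes must be positive")
  if (any(object@theta < 0) || any(object@theta > 180))
    return("theta must lie in [0, 180] degrees")
  if (any(object@r <= 0)) return("separation r must be positive")
  if (any(object@dielectric <= 0)) return("dielectric must be positive")
  n <- lengths(list(object@muA, object@muB, object@theta, object@r,
                    object@dielectric))
  if (length(unique(n[n > 1L])) > 1L)
    return("vector slots must share a common length (or be scalars)")
  TRUE
})

#' Construct a DipolePairState
#'
#' @param muA,muB dipole magnitudes (Debye). Recycled against the longest
#'   argument, so grids over \code{theta} or \code{r} are one call.
#' @param theta inter-dipole angle (degrees, 0-180).
#' @param r separation (Angstrom).
#' @param dielectric relative dielectric constant (default 78, bulk water).
#' @return A \linkS4class{DipolePairState}.
#' @examples
#' st <- DipolePairState(300, 300, theta = 135, r = 50)
#' dipoleForce(st)
#' @export
DipolePairState <- function(muA, muB = muA, theta, r, dielectric = 78) {
  new("DipolePairState", muA = as.numeric(muA), muB = as.numeric(muB),
      theta = as.numeric(theta), r = as.numeric(r),
      dielectric = as.numeric(dielectric))
}

#' BarrierSpec: free-energy barrier for Arrhenius timescale conversion
#'
#' @slot deltaG numeric, barrier height, kcal/mol, >= 0.
#' @slot temperature numeric, K, > 0 (default 300).
#' @slot prefactor numeric, attempt frequency, 1/s, > 0 (default 1e6 = 1/us).
#' @name BarrierSpec-class
#' @aliases BarrierSpec-class
#' @exportClass BarrierSpec
setClass("BarrierSpec",
         representation(deltaG = "numeric", temperature = "numeric",
                        prefactor = "numeric"))

setValidity("BarrierSpec", function(object) {
  if (any(object@deltaG < 0)) return("deltaG must be >= 0")
  if (any(object@temperature <= 0)) return("temperature must be positive")
  if (any(object@prefactor <= 0)) return("prefactor must be positive")
  TRUE
})

#' Construct a BarrierSpec
#'
#' @param deltaG barrier height, kcal/mol (vectorized).
#' @param temperature temperature, K.
#' @param prefactor attempt frequency, 1/s (default 1e6, i.e. 1 per
#'   microsecond).
#' @return A \linkS4class{BarrierSpec}.
#' @examples
#' arrheniusTimescale(BarrierSpec(20))  # ~3.7e8 s
#' @export
BarrierSpec <- function(deltaG, temperature = 300, prefactor = 1e6) {
  new("BarrierSpec", deltaG = as.numeric(deltaG),
      temperature = as.numeric(temperature),
      prefactor = as.numeric(prefactor))
}

## ---------------------------------------------------------------------------
## PCAFrame / LandscapeGrid
## ---------------------------------------------------------------------------

#' PCAFrame: principal-component reference frame of C-alpha coordinates
#'
#' Built from an ensemble of structures by iterative superposition onto the
#' converged ensemble mean followed by eigendecomposition of the covariance
#' matrix of the flattened C-alpha coordinates of a residue range.
#'
#' @slot residueRange integer(2), inclusive 1-based residue interval.
#' @slot meanCoords m x 3 matrix, converged mean C-alpha coordinates (A).
#' @slot eigenvectors 3m x k matrix, orthonormal columns, ordered by
#'   decreasing eigenvalue.
#' @slot eigenvalues numeric, A^2, non-increasing, >= 0.
#' @slot varianceFractions numeric, eigenvalue / trace, sums to 1 over all
#'   components.
#' @name PCAFrame-class
#' @aliases PCAFrame-class
#' @exportClass PCAFrame
setClass("PCAFrame",
         representation(residueRange = "integer", meanCoords = "matrix",
                        eigenvectors = "matrix", eigenvalues = "numeric",
                        varianceFractions = "numeric"))

setValidity("PCAFrame", function(object) {
  m <- nrow(object@meanCoords)
  if (ncol(object@meanCoords) != 3L) return("meanCoords must be m x 3")
  if (nrow(object@eigenvectors) != 3L * m)
    return("eigenvectors must be 3m-dimensional")
  ev <- object@eigenvalues
  if (any(ev < -1e-10)) return("eigenvalues must be >= 0")
  if (length(ev) > 1L && any(diff(ev) > 1e-10))
    return("eigenvalues must be sorted in non-increasing order")
  G <- crossprod(object@eigenvectors)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    return("eigenvectors must be orthonormal (tolerance 1e-8)")
  TRUE
})

#' LandscapeGrid: binned log-probability conformational landscape
#'
#' A 2D histogram of principal-component projections converted to
#' -kB T ln(N_i / N_0) in kcal/mol, where N_0 is the count of the most
#' populated bin. Empty bins are masked (NA). The minimum over occupied bins
#' is exactly 0.
#'
#' @slot pc1Edges,pc2Edges numeric bin edges along PC1 / PC2 (A).
#' @slot counts integer matrix, bins1 x bins2.
#' @slot values numeric matrix, kcal/mol, NA for empty bins.
#' @slot temperature numeric, K.
#' @name LandscapeGrid-class
#' @aliases LandscapeGrid-class
#' @exportClass LandscapeGrid
setClass("LandscapeGrid",
         representation(pc1Edges = "numeric", pc2Edges = "numeric",
                        counts = "matrix", values = "matrix",
                        temperature = "numeric"))

setValidity("LandscapeGrid", function(object) {
  if (!identical(dim(object@counts), dim(object@values)))
    return("counts and values must have identical dimensions")
  if (nrow(object@counts) != length(object@pc1Edges) - 1L ||
      ncol(object@counts) != length(object@pc2Edges) - 1L)
    return("grid dimensions inconsistent with bin edges")
  v <- object@values[!is.na(object@values)]
  if (!length(v)) return("landscape must contain at least one occupied bin")
  if (min(v) < -1e-9 || min(v) > 1e-9)
    return("minimum landscape value must be exactly 0")
  if (any(is.na(object@values) != (object@counts == 0L)))
    return("masked bins must be exactly the empty bins")
  TRUE
})

## ---------------------------------------------------------------------------
## SyntheticSpec
## ---------------------------------------------------------------------------

#' SyntheticSpec: recipe for a rigid-body Brownian multi-copy trajectory
#'
#' Describes a synthetic system of \code{nCopies} rigid copies of a template
#' structure diffusing in a periodic cubic box, with optional scripted
#' binding events and optional dipole-dipole attractive drift.
#'
#' @slot nCopies integer >= 1.
#' @slot boxEdge numeric, cubic box edge, Angstrom.
#' @slot template single-frame \linkS4class{Trajectory} (the rigid body).
#' @slot DTrans numeric, translational diffusion coefficient, m^2/s.
#' @slot DRot numeric, rotational diffusion coefficient, rad^2/s.
#' @slot dt numeric, time step, ns.
#' @slot nSteps integer >= 0, number of steps after the initial frame.
#' @slot seed integer, mandatory RNG seed.
#' @slot script data.frame with columns \code{chain_i}, \code{chain_j},
#'   \code{bind_time_ns}, \code{approach_speed_A_ns} (0 rows = no scripted
#'   events).
#' @slot dipoleCoupling logical, add deterministic dipolar attractive drift.
#' @name SyntheticSpec-class
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(nCopies = "integer", boxEdge = "numeric",
                        template = "Trajectory", DTrans = "numeric",
                        DRot = "numeric", dt = "numeric", nSteps = "integer",
                        seed = "integer", script = "data.frame",
                        dipoleCoupling = "logical"))

setValidity("SyntheticSpec", function(object) {
  if (object@nCopies < 1L) return("nCopies must be >= 1")
  if (object@boxEdge <= 0) return("boxEdge must be positive")
  if (object@DTrans < 0 || object@DRot < 0)
    return("diffusion coefficients must be >= 0")
  if (object@dt <= 0) return("dt must be positive")
  if (object@nSteps < 0L) return("nSteps must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (nrow(object@script)) {
    need <- c("chain_i", "chain_j", "bind_time_ns", "approach_speed_A_ns")
    if (!all(need %in% names(object@script)))
      return(paste("script needs columns:", paste(need, collapse = ", ")))
    if (any(object@script$chain_i == object@script$chain_j))
      return("scripted pairs must involve two distinct copies")
    if (any(object@script$chain_i > object@nCopies) ||
        any(object@script$chain_j > object@nCopies))
      return("scripted copy index exceeds nCopies")
    if (any(object@script$approach_speed_A_ns <= 0))
      return("approach speed must be positive")
  }
  TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults emulate the simulated study systems: three copies of a ~70
#' residue globular protein in a 100 Angstrom cubic periodic box (about 5 mM)
#' with a translational diffusion coefficient of 3e-11 m^2/s, mid-range of
#' the 2-5e-11 m^2/s observed for freely diffusing copies.
#'
#' @param nCopies number of rigid copies.
#' @param boxEdge cubic box edge, Angstrom.
#' @param template single-frame \linkS4class{Trajectory}; default
#'   \code{makeTemplate()}.
#' @param DTrans translational diffusion coefficient, m^2/s.
#' @param DRot rotational diffusion coefficient, rad^2/s.
#' @param dt time step, ns (default 0.1 ns, the package's default frame
#'   spacing).
#' @param nSteps number of Brownian steps after the initial frame.
#' @param seed RNG seed (mandatory).
#' @param script optional data.frame of scripted binding events with columns
#'   \code{chain_i}, \code{chain_j}, \code{bind_time_ns},
#'   \code{approach_speed_A_ns}.
#' @param dipoleCoupling logical; add a deterministic attractive drift along
#'   the inter-copy vector derived from the scalar dipole-dipole force.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- SyntheticSpec(nSteps = 10L, seed = 1L,
#'                       template = makeTemplate(n_residues = 10))
#' res <- generateTrajectory(spec)
#' nFrames(res$trajectory)
#' @export
SyntheticSpec <- function(nCopies = 3L, boxEdge = 100, template = makeTemplate(),
                          DTrans = 3e-11, DRot = 1e7, dt = 0.1,
                          nSteps = 100L, seed, script = NULL,
                          dipoleCoupling = FALSE) {
  if (missing(seed)) stop("seed is mandatory for a SyntheticSpec")
  if (is.null(script))
    script <- data.frame(chain_i = integer(), chain_j = integer(),
                         bind_time_ns = numeric(),
                         approach_speed_A_ns = numeric())
  new("SyntheticSpec", nCopies = as.integer(nCopies),
      boxEdge = as.numeric(boxEdge), template = template,
      DTrans = as.numeric(DTrans), DRot = as.numeric(DRot),
      dt = as.numeric(dt), nSteps = as.integer(nSteps),
      seed = as.integer(seed), script = script,
      dipoleCoupling = isTRUE(dipoleCoupling))
}
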