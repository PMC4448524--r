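#' @include topology-methods.R
NULL

#' Construct a Trajectory
#'
#' @param topology a \linkS4class{Topology}.
#' @param coords frames x atoms x 3 array (Angstrom). A single atoms x 3
#'   matrix is promoted to a one-frame trajectory.
#' @param boxEdge cubic box edge in Angstrom, or \code{NULL} for no box.
#' @param frameTimes frame times in ns; default 0.1 ns spacing starting at 0.
#' @return A \linkS4class{Trajectory}.
#' @export
Trajectory <- function(topology, coords, boxEdge = NULL, frameTimes = NULL) {
  if (is.matrix(coords))
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  if (is.null(frameTimes))
    frameTimes <- (seq_len(dim(coords)[1]) - 1L) * 0.1
  new("Trajectory", topology = topology, coords = coords,
      boxEdge = if (is.null(boxEdge)) numeric() else as.numeric(boxEdge),
      frameTimes = as.numeric(frameTimes))
}

#' @rdname accessors
#' @param frame optional frame index; when given, \code{coords} returns the
#'   atoms x 3 matrix of that frame.
#' @param ... unused.
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) return(x@coords)
  m <- x@coords[frame, , , drop = FALSE]
  matrix(m, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
})

#' @rdname accessors
#' @export
setMethod("topology", "Trajectory", function(object, ...) object@topology)

#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname accessors
#' @export
setMethod("chains", "Trajectory", function(x) x@topology@chains)

#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname accessors
#' @export
setMethod("boxEdge", "Trajectory", function(x)
  if (length(x@boxEdge)) x@boxEdge else NULL)

#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@frameTimes)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frame(s) x %d atoms; %s\n",
              nFrames(object), nAtoms(object),
              if (length(object@boxEdge))
                sprintf("cubic box %.1f A", object@boxEdge)
              else "no box"))
  t <- object@frameTimes
  cat(sprintf("  time %.3f .. %.3f ns; chains: %s\n",
              t[1], t[length(t)],
              paste(object@topology@chains, collapse = ", ")))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("series", "PairSeries", function(x) x@series)

#' @rdname accessors
#' @export
setMethod("chainPair", "PairSeries", function(x) x@chainPair)

#' @export
#' @describeIn PairSeries-class coerce to the underlying data.frame (adds
#'   \code{chain_a}, \code{chain_b} columns).
setMethod("as.data.frame", "PairSeries", function(x, ...) {
  cbind(chain_a = x@chainPair[1], chain_b = x@chainPair[2], x@series,
        stringsAsFactors = FALSE)
})

setMethod("show", "PairSeries", function(object) {
  s <- object@series
  cat(sprintf("PairSeries %s-%s: %d frames, %.3f .. %.3f ns\n",
              object@chainPair[1], object@chainPair[2], nrow(s),
              s$time_ns[1], s$time_ns[nrow(s)]))
  cat(sprintf("  com distance %.1f .. %.1f A; max contacts %s\n",
              min(s$com_distance_A), max(s$com_distance_A),
              max(s$n_contacts)))
  invisible(NULL)
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate: D = %.3e m^2/s (fit %.2f-%.2f ns, R^2 = %.3f)\n",
              object@D, object@fitWindow[1], object@fitWindow[2],
              object@fitQuality))
  invisible(NULL)
})

setMethod("show", "PCAFrame", function(object) {
  vf <- object@varianceFractions
  cat(sprintf("PCAFrame: residues %d-%d (%d C-alpha), %d components\n",
              object@residueRange[1], object@residueRange[2],
              nrow(object@meanCoords), length(object@eigenvalues)))
  cat(sprintf("  PC1/PC2 variance fractions: %.1f%% / %.1f%%\n",
              100 * vf[1], if (length(vf) > 1) 100 * vf[2] else 0))
  invisible(NULL)
})

setMethod("show", "LandscapeGrid", function(object) {
  occ <- sum(!is.na(object@values))
  cat(sprintf("LandscapeGrid: %d x %d bins, %d occupied, T = %.0f K, max %.2f kcal/mol\n",
              nrow(object@counts), ncol(object@counts), occ,
              object@temperature, max(object@values, na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d copies in %.0f A box, D_t = %.1e m^2/s, D_r = %.1e rad^2/s\n",
              object@nCopies, object@boxEdge, object@DTrans, object@DRot))
  cat(sprintf("  %d steps x %.3f ns, seed %d, %d scripted event(s)%s\n",
              object@nSteps, object@dt, object@seed, nrow(object@script),
              if (object@dipoleCoupling) ", dipole coupling on" else ""))
  invisible(NULL)
})
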