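#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers: \code{atoms} (atom
#' table), \code{chains} (chain ids), \code{nAtoms}, \code{nFrames},
#' \code{coords} (coordinate array), \code{boxEdge}, \code{frameTimes},
#' \code{series} (per-frame metric table of a \linkS4class{PairSeries}),
#' \code{chainPair}.
#'
#' @param x an object.
#' @return The slot contents; see each class page.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("topology", function(object, ...) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("series", function(x) standardGeneric("series"))

#' @rdname accessors
#' @export
setGeneric("chainPair", function(x) standardGeneric("chainPair"))

#' @rdname dipoleEnergy
#' @export
setGeneric("dipoleEnergy", function(state, ...) standardGeneric("dipoleEnergy"))

#' @rdname dipoleForce
#' @export
setGeneric("dipoleForce", function(state, ...) standardGeneric("dipoleForce"))

#' @rdname arrheniusTimescale
#' @export
setGeneric("arrheniusTimescale",
           function(spec, ...) standardGeneric("arrheniusTimescale"))

#' @rdname pcaProject
#' @export
setGeneric("pcaProject", function(frame, x, ...) standardGeneric("pcaProject"))
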