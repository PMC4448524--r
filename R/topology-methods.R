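#' @include AllGenerics.R
NULL

#' Construct a Topology from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{elesy}, \code{mass}, \code{charge}.
#'   The heavy-atom flag is derived from the element symbol.
#' @return A \linkS4class{Topology}.
#' @export
Topology <- function(atoms) {
  atoms$chain  <- as.character(atoms$chain)
  atoms$resno  <- as.integer(atoms$resno)
  atoms$resid  <- as.character(atoms$resid)
  atoms$elety  <- as.character(atoms$elety)
  atoms$elesy  <- as.character(atoms$elesy)
  atoms$heavy  <- toupper(atoms$elesy) != "H"
  atoms$mass   <- as.numeric(atoms$mass)
  atoms$charge <- as.numeric(atoms$charge)
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms, chains = unique(atoms$chain))
}

#' @rdname accessors
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("chains", "Topology", function(x) x@chains)

#' @rdname accessors
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' Atom indices of a chain
#'
#' @param topology a \linkS4class{Topology}.
#' @param chain chain identifier.
#' @param heavyOnly restrict to heavy (non-hydrogen) atoms.
#' @return Integer vector of atom indices (row positions in the atom table).
#' @export
chainAtomIndices <- function(topology, chain, heavyOnly = FALSE) {
  a <- atoms(topology)
  if (!chain %in% topology@chains)
    stop(sprintf("unknown chain id '%s'", chain))
  idx <- which(a$chain == chain)
  if (heavyOnly) idx <- idx[a$heavy[idx]]
  idx
}

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms (%d heavy), %d chain(s): %s\n",
              nrow(a), sum(a$heavy), length(object@chains),
              paste(object@chains, collapse = ", ")))
  cat(sprintf("  residues per chain: %s; total charge %.4f e\n",
              paste(vapply(object@chains, function(ch)
                length(unique(a$resno[a$chain == ch])), 1L),
                collapse = ", "),
              sum(a$charge)))
  invisible(NULL)
})
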