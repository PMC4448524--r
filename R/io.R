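#' @include trajectory-methods.R
NULL

## element -> mass (amu) and PQR radius (A) fallback tables; bio3d::atom2mass
## covers the common cases, these guard exotic/unknown symbols.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, FE = 55.845, ZN = 65.38)
.ELEMENT_RADIUS <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                     P = 1.80)

.elementMass <- function(elesy) {
  m <- unname(.ELEMENT_MASS[toupper(elesy)])
  if (anyNA(m)) {
    miss <- unique(toupper(elesy)[is.na(m)])
    mm <- tryCatch(suppressWarnings(bio3d::atom2mass(miss)),
                   error = function(e) rep(NA_real_, length(miss)))
    lut <- stats::setNames(mm, miss)
    m[is.na(m)] <- lut[toupper(elesy)[is.na(m)]]
    m[is.na(m)] <- 12.011  # last resort: treat as carbon
  }
  m
}

.elementRadius <- function(elesy) {
  r <- unname(.ELEMENT_RADIUS[toupper(elesy)])
  r[is.na(r)] <- 1.70
  r
}

## Pre-parse scan of a PDB/PQR file: returns per-model atom-line counts and
## raises line-numbered parse errors before delegating to bio3d.
.scanPdbLines <- function(path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (format == "pdb") {
      if (nchar(ln) < 54)
        stop(sprintf("parse error at line %d: ATOM record too short", i))
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      if (anyNA(xyz))
        stop(sprintf("parse error at line %d: non-numeric coordinates", i))
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 10)
        stop(sprintf("parse error at line %d: PQR record needs 10+ fields", i))
      if (anyNA(suppressWarnings(as.numeric(f[(length(f) - 4):length(f)]))))
        stop(sprintf("parse error at line %d: non-numeric PQR fields", i))
    }
  }
  modelStarts <- which(startsWith(lines, "MODEL"))
  if (length(modelStarts)) {
    modelEnds <- which(startsWith(lines, "ENDMDL"))
    if (length(modelEnds) != length(modelStarts))
      stop("parse error: unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(modelStarts), function(k)
      sum(isAtom[modelStarts[k]:modelEnds[k]]), 1L)
  } else {
    counts <- sum(isAtom)
  }
  counts
}

#' Read a structure file (PDB or PQR)
#'
#' Parses a single-snapshot structure into the package's data model. PQR
#' files supply per-atom partial charges; plain PDB yields zero charges (and
#' any downstream dipole computation on such a topology warns). 1-based PDB
#' residue numbering is preserved verbatim; no periodic wrapping is applied
#' on read.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"pqr"}, or \code{"auto"} (by file
#'   extension, default).
#' @param boxEdge optional cubic box edge (Angstrom) to attach.
#' @return A single-frame \linkS4class{Trajectory}.
#' @examples
#' tpl <- makeTemplate(n_residues = 5)
#' f <- tempfile(fileext = ".pdb")
#' writeTrajectory(tpl, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "pqr"),
                          boxEdge = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  .scanPdbLines(path, format)
  pdb <- if (format == "pqr") bio3d::read.pqr(path)
         else suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  elesy <- suppressWarnings(bio3d::atom2ele(pdb, rescue = TRUE))
  atomTable <- data.frame(
    chain = chain, resno = a$resno, resid = a$resid, elety = a$elety,
    elesy = elesy, mass = .elementMass(elesy),
    charge = if (format == "pqr") a$o else 0,
    stringsAsFactors = FALSE)
  key <- paste(atomTable$chain, atomTable$resno, atomTable$elety, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("integrity error: duplicate atom key '%s %d %s'",
                 atomTable$chain[anyDuplicated(key)],
                 atomTable$resno[anyDuplicated(key)],
                 atomTable$elety[anyDuplicated(key)]))
  topo <- Topology(atomTable)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  Trajectory(topo, xyz, boxEdge = boxEdge, frameTimes = 0)
}

#' Read a multi-model PDB trajectory
#'
#' MODEL/ENDMDL blocks become frames in file order. Every model must carry
#' exactly the topology's atom count; a mismatch is an integrity error naming
#' the offending frame. Frame times default to 0.1 ns spacing when the file
#' carries none (PDB has no time record), overridable via \code{dt} or
#' \code{frameTimes}.
#'
#' @param path multi-model PDB file.
#' @param topology a \linkS4class{Topology} describing the atoms (e.g. from
#'   \code{readStructure} on a PQR with charges).
#' @param dt frame spacing in ns (default 0.1).
#' @param frameTimes explicit frame times in ns (overrides \code{dt}).
#' @param boxEdge optional cubic box edge, Angstrom.
#' @return A \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, topology, dt = 0.1, frameTimes = NULL,
                           boxEdge = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  counts <- .scanPdbLines(path, "pdb")
  nTopo <- nAtoms(topology)
  bad <- which(counts != nTopo)
  if (length(bad))
    stop(sprintf(
      "integrity error: frame %d has %d atoms but topology has %d",
      bad[1], counts[bad[1]], nTopo))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  co <- array(NA_real_, dim = c(nf, nTopo, 3))
  for (f in seq_len(nf))
    co[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (is.null(frameTimes)) frameTimes <- (seq_len(nf) - 1L) * dt
  Trajectory(topology, co, boxEdge = boxEdge, frameTimes = frameTimes)
}

#' Write a trajectory (or single-frame structure) to multi-model PDB or PQR
#'
#' PDB output stores coordinates to 0.001 Angstrom; round-tripping through
#' \code{readTrajectory} reproduces coordinates to that precision. PQR output
#' (single frame only) carries the topology's partial charges and
#' element-based radii.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output file.
#' @param format \code{"pdb"} (default; multi-model when several frames) or
#'   \code{"pqr"}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  a <- atoms(trajectory)
  co <- coords(trajectory)
  nf <- dim(co)[1]
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nAtoms(trajectory))
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(co[f, , ]))
  if (format == "pqr") {
    if (nf > 1L) stop("PQR output is single-frame; write PDB for trajectories")
    bio3d::write.pqr(file = path, xyz = xyz[1, ], resno = a$resno,
                     resid = a$resid, eleno = seq_len(nrow(a)),
                     elety = a$elety, chain = a$chain,
                     o = a$charge, b = .elementRadius(a$elesy))
  } else {
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                     resid = a$resid, eleno = seq_len(nrow(a)),
                     elety = a$elety, chain = a$chain,
                     elesy = a$elesy)
  }
  invisible(path)
}

#' Write a table of records as CSV
#'
#' Comma-separated, header row, '.' decimal separator; byte-stable for
#' identical inputs. Refuses empty record sets (an empty output file would be
#' indistinguishable from a failed stage).
#'
#' @param records non-empty data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop("refusing to write an empty record set")
  status <- try(utils::write.csv(records, path, row.names = FALSE,
                                 quote = FALSE), silent = TRUE)
  if (inherits(status, "try-error"))
    stop(sprintf("I/O error writing %s", path))
  invisible(path)
}
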