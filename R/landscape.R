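#' @include geometry.R
NULL

## Extract the residue-range C-alpha coordinate matrix of one chain from a
## single frame; errors name the first missing residue.
.caCoords <- function(trajectory, frame, chain, residueRange) {
  topo <- topology(trajectory); a <- atoms(trajectory)
  want <- seq(residueRange[1], residueRange[2])
  idx <- which(a$chain == chain & a$elety == "CA" & a$resno %in% want)
  got <- a$resno[idx]
  miss <- setdiff(want, got)
  if (length(miss))
    stop(sprintf("missing C-alpha for residue %d (chain %s)", miss[1], chain))
  idx <- idx[order(got)]
  coords(trajectory, frame = frame)[idx, , drop = FALSE]
}

## Normalize ensemble input to a list of m x 3 C-alpha matrices.
.ensembleList <- function(ensemble, residueRange, chain) {
  if (is(ensemble, "Trajectory")) {
    if (is.null(chain)) chain <- topology(ensemble)@chains[1]
    lapply(seq_len(nFrames(ensemble)), function(f)
      .caCoords(ensemble, f, chain, residueRange))
  } else if (is.list(ensemble)) {
    lapply(ensemble, function(m) {
      m <- rbind(m)
      if (ncol(m) != 3L) stop("ensemble matrices must be m x 3")
      m
    })
  } else stop("ensemble must be a Trajectory or a list of m x 3 matrices")
}

## Superpose X (m x 3) onto reference (m x 3): center both, rotate X.
.superpose <- function(X, ref) {
  cx <- colMeans(X); cr <- colMeans(ref)
  Xc <- sweep(X, 2, cx)
  R <- .kabsch(Xc, sweep(ref, 2, cr))
  sweep(Xc %*% t(R), 2, cr, "+")
}

#' Build a principal-component reference frame from a structural ensemble
#'
#' All structures are iteratively superposed onto the running ensemble mean
#' of the residue-range C-alpha coordinates (re-aligning and re-averaging
#' until the mean moves less than \code{tol}, at most \code{maxIter}
#' rounds), then the covariance matrix of the flattened 3m coordinates is
#' eigendecomposed. Variance fractions are eigenvalue over trace.
#'
#' @param ensemble a \linkS4class{Trajectory} whose frames are the ensemble
#'   members, or a list of m x 3 C-alpha coordinate matrices.
#' @param residueRange inclusive 1-based residue interval (default 2-70;
#'   ignored when matrices are supplied directly).
#' @param chain chain to extract (default: first chain).
#' @param maxIter maximum alignment iterations (default 10).
#' @param tol convergence threshold on the RMS mean shift, Angstrom
#'   (default 1e-6).
#' @return A \linkS4class{PCAFrame}.
#' @export
buildPCAFrame <- function(ensemble, residueRange = c(2L, 70L), chain = NULL,
                          maxIter = 10L, tol = 1e-6) {
  residueRange <- as.integer(residueRange)
  xs <- .ensembleList(ensemble, residueRange, chain)
  if (length(xs) < 2L) stop("need >= 2 structures to build a PCA frame")
  m <- nrow(xs[[1]])
  if (any(vapply(xs, nrow, 1L) != m))
    stop("all ensemble structures must have the same atom count")

  ref <- xs[[1]]
  for (it in seq_len(maxIter)) {
    aligned <- lapply(xs, .superpose, ref = ref)
    newMean <- Reduce(`+`, aligned) / length(aligned)
    shift <- sqrt(mean((newMean - ref)^2))
    ref <- newMean
    if (shift < tol) break
  }
  aligned <- lapply(xs, .superpose, ref = ref)

  X <- t(vapply(aligned, function(x) as.vector(t(x)), numeric(3L * m)))
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (sum(ev) < 1e-12)
    stop("degenerate ensemble: all structures identical (zero covariance)")
  new("PCAFrame", residueRange = residueRange, meanCoords = ref,
      eigenvectors = eg$vectors, eigenvalues = ev,
      varianceFractions = ev / sum(ev))
}

#' Project structures onto a PCA frame
#'
#' Each snapshot's residue-range C-alpha coordinates are superposed onto the
#' frame's mean structure and the centered, flattened coordinates are dotted
#' with the leading eigenvectors. Rigid transforms of the input leave the
#' projection unchanged (alignment removes them).
#'
#' @param frame a \linkS4class{PCAFrame}.
#' @param x a \linkS4class{Trajectory}, an m x 3 matrix, or a list of such
#'   matrices.
#' @param nComponents number of components to return (default 2).
#' @param chain chain to extract from a trajectory (default first).
#' @param ... unused.
#' @return n x nComponents matrix of scores (Angstrom along each PC).
#' @rdname pcaProject
#' @export
setMethod("pcaProject", "PCAFrame",
          function(frame, x, nComponents = 2L, chain = NULL, ...) {
  xs <- if (is.matrix(x)) list(rbind(x))
        else .ensembleList(x, frame@residueRange, chain)
  m <- nrow(frame@meanCoords)
  if (any(vapply(xs, nrow, 1L) != m))
    stop("snapshot atom count does not match the PCA frame")
  mu <- as.vector(t(frame@meanCoords))
  V <- frame@eigenvectors[, seq_len(nComponents), drop = FALSE]
  out <- t(vapply(xs, function(s) {
    al <- .superpose(s, frame@meanCoords)
    as.numeric(crossprod(V, as.vector(t(al)) - mu))
  }, numeric(nComponents)))
  colnames(out) <- paste0("PC", seq_len(nComponents))
  out
})

#' Binned log-probability conformational landscape
#'
#' 2D histogram of PC scores converted to \eqn{-k_B T \ln(N_i/N_0)} in
#' kcal/mol, where \eqn{N_0} is the count of the most populated bin (ties
#' all map to 0). Empty bins are masked. Doubling every count leaves the
#' landscape unchanged (only count ratios matter).
#'
#' @param points n x 2 matrix of (PC1, PC2) scores.
#' @param bins number of bins per axis (default 40).
#' @param temperature temperature, K (default 300).
#' @param pad fractional padding of the data range (default 0.05).
#' @return A \linkS4class{LandscapeGrid}.
#' @export
logProbLandscape <- function(points, bins = 40L, temperature = 300,
                             pad = 0.05) {
  points <- rbind(points)
  if (nrow(points) < 1L) stop("need at least one point")
  edges <- lapply(1:2, function(k) {
    r <- range(points[, k])
    if (diff(r) == 0) r <- r + c(-1, 1)
    w <- diff(r) * pad
    seq(r[1] - w, r[2] + w, length.out = bins + 1L)
  })
  ix <- findInterval(points[, 1], edges[[1]], rightmost.closed = TRUE)
  iy <- findInterval(points[, 2], edges[[2]], rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(nrow(points)))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  kT <- physicalConstants()$R_kcal_mol_K * temperature
  vals <- -kT * log(counts / max(counts))
  vals[counts == 0L] <- NA_real_
  new("LandscapeGrid", pc1Edges = edges[[1]], pc2Edges = edges[[2]],
      counts = counts, values = vals, temperature = temperature)
}

#' Flatten a LandscapeGrid to a table
#'
#' @param grid a \linkS4class{LandscapeGrid}.
#' @param dropEmpty drop masked (empty) bins (default TRUE).
#' @return data.frame with columns \code{pc1_bin_center},
#'   \code{pc2_bin_center}, \code{count}, \code{value_kcal_mol}.
#' @export
landscapeTable <- function(grid, dropEmpty = TRUE) {
  e1 <- grid@pc1Edges; e2 <- grid@pc2Edges
  c1 <- (e1[-length(e1)] + e1[-1]) / 2
  c2 <- (e2[-length(e2)] + e2[-1]) / 2
  df <- expand.grid(pc1_bin_center = c1, pc2_bin_center = c2,
                    KEEP.OUT.ATTRS = FALSE)
  df$count <- as.vector(grid@counts)
  df$value_kcal_mol <- as.vector(grid@values)
  if (dropEmpty) df <- df[df$count > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Serialize / restore a PCAFrame as plain text
#'
#' The file carries the residue range, the mean C-alpha coordinates, the
#' eigenvalues and the eigenvectors in a simple sectioned text format, so a
#' frame built once can be reused across analyses.
#'
#' @param frame a \linkS4class{PCAFrame}.
#' @param path output / input file.
#' @return \code{writePCAFrame}: \code{path} invisibly;
#'   \code{readPCAFrame}: a \linkS4class{PCAFrame}.
#' @export
writePCAFrame <- function(frame, path) {
  con <- file(path, "w"); on.exit(close(con))
  m <- nrow(frame@meanCoords); k <- length(frame@eigenvalues)
  writeLines(c("# PCAFrame v1",
               sprintf("residue_range %d %d", frame@residueRange[1],
                       frame@residueRange[2]),
               sprintf("n_atoms %d", m), sprintf("n_components %d", k),
               "mean_coords"), con)
  utils::write.table(format(frame@meanCoords, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("eigenvalues", con)
  writeLines(paste(format(frame@eigenvalues, digits = 17), collapse = " "), con)
  writeLines("eigenvectors", con)
  utils::write.table(format(frame@eigenvectors, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePCAFrame
#' @export
readPCAFrame <- function(path) {
  lines <- readLines(path)
  rng <- as.integer(strsplit(lines[2], " ")[[1]][2:3])
  m <- as.integer(strsplit(lines[3], " ")[[1]][2])
  k <- as.integer(strsplit(lines[4], " ")[[1]][2])
  readBlock <- function(start, n) {
    matrix(as.numeric(unlist(strsplit(trimws(lines[start:(start + n - 1)]),
                                      "\\s+"))), nrow = n, byrow = TRUE)
  }
  mean0 <- readBlock(6, m)
  ev <- as.numeric(strsplit(trimws(lines[6 + m + 1]), "\\s+")[[1]])
  vecs <- readBlock(6 + m + 3, 3L * m)
  new("PCAFrame", residueRange = rng, meanCoords = mean0,
      eigenvectors = vecs[, seq_len(k), drop = FALSE],
      eigenvalues = ev[seq_len(k)],
      varianceFractions = ev[seq_len(k)] / sum(ev))
}
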