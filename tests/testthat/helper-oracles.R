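# Independent oracles kept deliberately separate from the package internals.

# Rotation angle of a 3x3 rotation matrix via quaternion extraction
# (independent of the trace formula used by orientationAngle).
quaternionAngle <- function(R) {
  qw2 <- (1 + R[1, 1] + R[2, 2] + R[3, 3]) / 4
  w <- sqrt(max(0, qw2))
  2 * acos(min(1, w)) * 180 / pi
}

rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Brute-force all-pairs contact count (atoms convention): no vectorized
# distance matrix, no minimum imaging shortcuts.
bruteContacts <- function(xA, xB, cutoff, boxEdge = NULL) {
  near <- function(p, q) {
    d <- p - q
    if (!is.null(boxEdge)) d <- d - boxEdge * round(d / boxEdge)
    sqrt(sum(d^2)) <= cutoff
  }
  inA <- logical(nrow(xA)); inB <- logical(nrow(xB))
  for (i in seq_len(nrow(xA))) for (j in seq_len(nrow(xB)))
    if (near(xA[i, ], xB[j, ])) { inA[i] <- TRUE; inB[j] <- TRUE }
  sum(inA) + sum(inB)
}

# Minimal hand-written PDB/PQR fixtures (written at test time, never stored).
toyPdbLines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
  "ATOM      3  O   GLY B   2       0.000   3.000   0.000  1.00  0.00           O",
  "END")

toyPqrLines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  0.5000 1.5500",
  "ATOM      2  CA  ALA A   1       1.500   0.000   0.000 -0.5000 1.7000",
  "ATOM      3  O   GLY B   2       0.000   3.000   0.000  0.0000 1.5200",
  "END")

writeToyFile <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Two-chain fixture with controllable nearest heavy-atom separation: each
# chain is a 5-atom cluster (4 heavy + 1 H). The closest heavy pair (the two
# CA atoms of residue 1) spans exactly `gap`; all other heavy atoms trail
# at least 3 A behind. Hydrogens sit `hGap` apart when given (else trail).
twoClusterTrajectory <- function(gap, hGap = NULL, boxEdge = NULL) {
  mk <- function(chain) {
    data.frame(chain = chain, resno = c(1, 1, 1, 2, 2),
               resid = c("ALA", "ALA", "ALA", "GLY", "GLY"),
               elety = c("CA", "N", "HN", "CA", "CB"),
               elesy = c("C", "N", "H", "C", "C"),
               mass = c(12.011, 14.007, 1.008, 12.011, 12.011), charge = 0)
  }
  topo <- Topology(rbind(mk("A"), mk("B")))
  hx <- if (is.null(hGap)) gap / 2 + 2 else hGap / 2
  side <- function(s) {  # s = -1 for chain A, +1 for chain B
    rbind(c(s * gap / 2, 0, 0), c(s * (gap / 2 + 3), 1, 0),
          c(s * hx, 0, 0.5), c(s * (gap / 2 + 4), 0, 1),
          c(s * (gap / 2 + 5), -1, 0))
  }
  Trajectory(topo, rbind(side(-1), side(1)), boxEdge = boxEdge)
}
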