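#' @include trajectory-methods.R
NULL

.AMU <- c(N = 14.007, C = 12.011, O = 15.999, H = 1.008)

## axis-angle rotation matrix (Rodrigues)
.rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

.chainIds <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("C%02d", seq_len(n))
}

#' Build the deterministic pseudo-protein template
#'
#' Constructs a compact globular pseudo-protein: residues placed on a
#' volume-filling Fibonacci spiral inside a ~11 Angstrom ball, nine atoms
#' per residue (eight heavy: N, CA, C, O, CB, CG, CD, CE; one hydrogen), so
#' the default 70 residues carry 560 heavy atoms. Partial charges are
#' constructed to sum to zero exactly with the dipole moment along +z
#' scaled to \code{dipole_target} (the 200-300 D range typical of a small
#' globular protein motivates the 250 D default). The construction is fully
#' deterministic: identical arguments give bit-identical output.
#'
#' @param n_residues number of residues (>= 3).
#' @param dipole_target dipole magnitude, Debye.
#' @return A single-frame \linkS4class{Trajectory} (chain "A"), centered on
#'   its center of mass.
#' @examples
#' tpl <- makeTemplate()
#' sum(atoms(tpl)$charge)                     # 0 (construction constraint)
#' @export
makeTemplate <- function(n_residues = 70L, dipole_target = 250) {
  if (n_residues < 3L) stop("need at least 3 residues")
  n <- as.integer(n_residues)
  golden <- pi * (3 - sqrt(5))
  R <- 11 * (n / 70)^(1/3)                 # keep density constant
  i <- seq_len(n)
  r <- R * ((i - 0.5) / n)^(1/3)
  zc <- 1 - 2 * (i - 0.5) / n
  rho <- sqrt(pmax(0, 1 - zc^2))
  base <- cbind(r * rho * cos(golden * i), r * rho * sin(golden * i), r * zc)

  ## local orthonormal frame per residue (deterministic)
  atomsPerRes <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "HN"),
    elesy = c("N", "C", "C", "O", "C", "C", "C", "C", "H"),
    stringsAsFactors = FALSE)
  offs <- rbind(c(-1.45, 0, 0), c(0, 0, 0), c(1.50, 0, 0), c(1.95, 1.10, 0),
                c(0, -1.52, 0), c(0, -2.60, 1.05), c(0.95, -3.55, 1.05),
                c(0.95, -4.60, 2.05), c(-1.85, 0.85, 0))
  coordsList <- vector("list", n)
  for (k in i) {
    u3 <- base[k, ]; nu <- sqrt(sum(u3^2))
    u3 <- if (nu > 1e-9) u3 / nu else c(0, 0, 1)
    helper <- if (abs(u3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u1 <- helper - sum(helper * u3) * u3; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(u3[2] * u1[3] - u3[3] * u1[2],
            u3[3] * u1[1] - u3[1] * u1[3],
            u3[1] * u1[2] - u3[2] * u1[1])
    B <- rbind(u1, u2, u3)                # local frame rows
    coordsList[[k]] <- sweep(offs %*% B, 2, base[k, ], "+")
  }
  xyz <- do.call(rbind, coordsList)
  tab <- data.frame(
    chain = "A", resno = rep(i, each = nrow(atomsPerRes)),
    resid = "ALA",
    elety = rep(atomsPerRes$elety, n), elesy = rep(atomsPerRes$elesy, n),
    mass = unname(.AMU[rep(atomsPerRes$elesy, n)]), charge = 0,
    stringsAsFactors = FALSE)

  ## charges: zero-sum pattern proportional to centered z, scaled to target
  com <- colSums(xyz * tab$mass) / sum(tab$mass)
  xyz <- sweep(xyz, 2, com)
  p <- xyz[, 3] - mean(xyz[, 3])           # sums to zero exactly
  muRawD <- sqrt(sum(colSums(xyz * p)^2)) * .const$eA_to_debye
  if (muRawD < 1e-6)
    stop("unreachable dipole target: degenerate charge pattern")
  tab$charge <- p * (dipole_target / muRawD)
  tab$charge <- tab$charge - mean(tab$charge)   # exact zero total
  Trajectory(Topology(tab), xyz, frameTimes = 0)
}

#' Construct a perfect C2-symmetric dimer from a template
#'
#' The second copy is the first rotated 180 degrees about an axis through
#' the pair midpoint (the z axis through the origin), so the
#' \code{\link{orientationAngle}} of the pair is exactly 180 degrees and
#' the center-of-mass distance equals \code{comDistance}.
#'
#' @param template single-frame \linkS4class{Trajectory} (single chain).
#' @param comDistance center-of-mass separation, Angstrom (default 25).
#' @return Single-frame two-chain \linkS4class{Trajectory} (chains A, B).
#' @export
makeC2Dimer <- function(template, comDistance = 25) {
  a <- atoms(template)
  x <- coords(template, frame = 1)
  com <- centerOfMass(x, a$mass)
  x <- sweep(x, 2, com)                          # center the copy
  xA <- sweep(x, 2, c(-comDistance / 2, 0, 0), "+")
  R2 <- diag(c(-1, -1, 1))                       # 180 deg about z
  xB <- xA %*% R2                                # rotate about the midpoint
  tabA <- a; tabA$chain <- "A"
  tabB <- a; tabB$chain <- "B"
  Trajectory(Topology(rbind(tabA, tabB)), rbind(xA, xB), frameTimes = 0)
}

#' Generate a rigid-body Brownian multi-copy trajectory
#'
#' Each free copy performs, per step, a Gaussian translation of variance
#' 2 D_trans dt per axis and a rotation about a random axis with angle of
#' variance 2 D_rot dt. Copies are placed with all pairwise center-of-mass
#' separations >= 30 Angstrom in the initial frame (re-sampled up to 1000
#' times). Scripted pairs switch to a deterministic mutual approach at
#' their bind time and remain attached once the contact distance (75\% of
#' the template gyration diameter) is reached. Stored coordinates are
#' wrapped by chain center of mass, so molecules never straddle the
#' boundary. With \code{dipoleCoupling}, free pairs additionally drift
#' along their inter-COM vector with velocity mobility x force from the
#' scalar dipole-dipole interaction (Einstein mobility D / kB T).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{trajectory} (a \linkS4class{Trajectory}) and
#'   \code{groundTruth}: true D_trans/D_rot, template dipole magnitude,
#'   realized event table (scripted bind times plus attained contact
#'   times), the seed and a spec echo.
#' @export
generateTrajectory <- function(spec) {
  set.seed(spec@seed)
  tplTopo <- topology(spec@template)
  tplAtoms <- atoms(spec@template)
  X0 <- coords(spec@template, frame = 1)
  X0 <- sweep(X0, 2, centerOfMass(X0, tplAtoms$mass))
  nC <- spec@nCopies; L <- spec@boxEdge
  natom <- nrow(X0)
  gyr <- gyrationDiameter(X0, tplAtoms$mass)
  dContact <- 0.75 * gyr
  dipole <- suppressWarnings(dipoleMoment(X0, tplAtoms$charge,
                                          tplAtoms$mass))

  ## initial placement: >= 30 A pairwise COM separation (minimum image)
  placeOK <- FALSE
  for (try in seq_len(1000L)) {
    coms <- matrix(stats::runif(3 * nC, 0, L), ncol = 3)
    ok <- TRUE
    if (nC > 1L)
      for (p in seq_len(nC - 1L)) for (q in (p + 1L):nC)
        if (pbcDistance(coms[p, ], coms[q, ], L) < 30) ok <- FALSE
    if (ok) { placeOK <- TRUE; break }
  }
  if (!placeOK)
    stop("could not place copies >= 30 A apart after 1000 tries; ",
         "box too small for nCopies")
  rots <- lapply(seq_len(nC), function(k)
    .rotationMatrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi)))

  sdT <- sqrt(2 * (spec@DTrans * 1e11) * spec@dt)       # A per axis per step
  sdR <- sqrt(2 * (spec@DRot * 1e-9) * spec@dt)         # rad per step
  kT <- physicalConstants()$kB_J_K * 300
  mobility <- spec@DTrans / kT                          # m/s per N

  script <- spec@script
  scriptState <- if (nrow(script))
    data.frame(script, attached = FALSE, contact_time_ns = NA_real_,
               offset = I(vector("list", nrow(script))))
  else NULL

  nf <- spec@nSteps + 1L
  co <- array(NA_real_, dim = c(nf, nC * natom, 3))
  writeFrame <- function(f) {
    for (k in seq_len(nC)) {
      cw <- coms[k, ] - L * floor(coms[k, ] / L)
      rows <- ((k - 1L) * natom + 1L):(k * natom)
      co[f, rows, ] <<- sweep(X0 %*% t(rots[[k]]), 2, cw, "+")
    }
  }
  writeFrame(1L)

  muD <- sqrt(sum(dipole^2))
  for (step in seq_len(spec@nSteps)) {
    tNow <- step * spec@dt
    attachedTo <- rep(0L, nC)
    approaching <- rep(FALSE, nC)
    if (!is.null(scriptState)) {
      for (e in seq_len(nrow(scriptState))) {
        if (scriptState$attached[e])
          attachedTo[scriptState$chain_j[e]] <- scriptState$chain_i[e]
        else if (tNow >= scriptState$bind_time_ns[e])
          approaching[scriptState$chain_j[e]] <- TRUE
      }
    }
    ## free Brownian updates
    for (k in seq_len(nC)) {
      if (attachedTo[k] || approaching[k]) next
      coms[k, ] <- coms[k, ] + stats::rnorm(3, 0, sdT)
      if (sdR > 0)
        rots[[k]] <- .rotationMatrix(stats::rnorm(3),
                                     stats::rnorm(1, 0, sdR)) %*% rots[[k]]
    }
    ## optional dipolar drift between free pairs
    if (spec@dipoleCoupling && muD > 0 && nC > 1L) {
      for (p in seq_len(nC - 1L)) for (q in (p + 1L):nC) {
        if (attachedTo[p] || attachedTo[q] || approaching[p] ||
            approaching[q]) next
        dvec <- coms[p, ] - coms[q, ]
        dvec <- dvec - L * round(dvec / L)
        rr <- sqrt(sum(dvec^2))
        if (rr < 1e-6 || rr > L / 2) next
        th <- vectorAngle(as.numeric(rots[[p]] %*% dipole),
                          as.numeric(rots[[q]] %*% dipole))
        f <- dipoleForce(DipolePairState(muD, muD, th, rr, 78))
        vel <- mobility * f$force_pN * 1e-12 * 1e10 * 1e-9  # A per ns
        dstep <- min(vel * spec@dt, 0.5) * (if (f$attractive) 1 else -1)
        u <- dvec / rr
        coms[p, ] <- coms[p, ] - u * dstep / 2
        coms[q, ] <- coms[q, ] + u * dstep / 2
      }
    }
    ## scripted approaches / attachments
    if (!is.null(scriptState)) {
      for (e in seq_len(nrow(scriptState))) {
        i <- scriptState$chain_i[e]; j <- scriptState$chain_j[e]
        if (scriptState$attached[e]) {
          coms[j, ] <- coms[i, ] + scriptState$offset[[e]]
        } else if (tNow >= scriptState$bind_time_ns[e]) {
          dvec <- coms[i, ] - coms[j, ]
          dvec <- dvec - L * round(dvec / L)
          rr <- sqrt(sum(dvec^2))
          stepLen <- scriptState$approach_speed_A_ns[e] * spec@dt
          if (rr - stepLen <= dContact) {
            u <- dvec / rr
            scriptState$offset[[e]] <- -u * dContact
            scriptState$attached[e] <- TRUE
            scriptState$contact_time_ns[e] <- tNow
            coms[j, ] <- coms[i, ] - u * dContact
          } else {
            coms[j, ] <- coms[j, ] + dvec / rr * stepLen
          }
        }
      }
    }
    writeFrame(step + 1L)
  }

  ## assemble multi-chain topology
  ids <- .chainIds(nC)
  tabs <- lapply(seq_len(nC), function(k) {
    t <- tplAtoms; t$chain <- ids[k]; t
  })
  topo <- Topology(do.call(rbind, tabs))
  traj <- Trajectory(topo, co, boxEdge = L,
                     frameTimes = (seq_len(nf) - 1L) * spec@dt)
  gtEvents <- if (!is.null(scriptState))
    data.frame(chain_i = ids[scriptState$chain_i],
               chain_j = ids[scriptState$chain_j],
               bind_time_ns = scriptState$bind_time_ns,
               contact_time_ns = scriptState$contact_time_ns)
  else data.frame(chain_i = character(), chain_j = character(),
                  bind_time_ns = numeric(), contact_time_ns = numeric())
  list(trajectory = traj,
       groundTruth = list(
         D_trans = spec@DTrans, D_rot = spec@DRot,
         dipole_D = muD, gyration_diameter_A = gyr,
         contact_distance_A = dContact, events = gtEvents,
         seed = spec@seed,
         spec = list(nCopies = nC, boxEdge = L, dt = spec@dt,
                     nSteps = spec@nSteps,
                     dipoleCoupling = spec@dipoleCoupling)))
}

#' Synthetic conformational ensemble with known mode structure
#'
#' Displaces the residue-range C-alpha coordinates of a template along
#' synthetic orthonormal modes (constructed orthogonal to rigid-body
#' translations and infinitesimal rotations, so superposition cannot absorb
#' them) with exactly standardized scores, giving an ensemble whose
#' covariance has a known mode decomposition — the ground truth for PCA
#' recovery tests.
#'
#' @param template single-frame \linkS4class{Trajectory}.
#' @param nStructures ensemble size (default 200).
#' @param sdAmplitudes per-mode displacement standard deviations, Angstrom
#'   (default \code{c(1, 0.5)}: a 4:1 variance ratio, i.e. 80\%/20\% of the
#'   variability).
#' @param residueRange inclusive residue interval (default 2 to n-1).
#' @param seed RNG seed.
#' @return list: \code{structures} (list of m x 3 C-alpha matrices),
#'   \code{modes} (3m x k orthonormal), \code{scores} (n x k, sample sd
#'   exactly \code{sdAmplitudes}), \code{residueRange}.
#' @export
makeModeEnsemble <- function(template, nStructures = 200L,
                             sdAmplitudes = c(1, 0.5), residueRange = NULL,
                             seed = 1L) {
  set.seed(seed)
  a <- atoms(template)
  nres <- length(unique(a$resno))
  if (is.null(residueRange)) residueRange <- c(2L, nres - 1L)
  ca <- .caCoords(template, 1L, a$chain[1], residueRange)
  m <- nrow(ca)
  mu <- as.vector(t(ca))

  ## rigid-body subspace: 3 translations + 3 infinitesimal rotations
  centered <- sweep(ca, 2, colMeans(ca))
  rig <- matrix(0, 3 * m, 6)
  for (ax in 1:3) rig[seq(ax, 3 * m, by = 3), ax] <- 1
  cross <- function(v, w) c(v[2] * w[3] - v[3] * w[2],
                            v[3] * w[1] - v[1] * w[3],
                            v[1] * w[2] - v[2] * w[1])
  for (ax in 1:3) {
    e <- diag(3)[ax, ]
    rig[, 3 + ax] <- as.vector(t(t(apply(centered, 1, cross, w = e))))
  }
  Qrig <- qr.Q(qr(rig))

  k <- length(sdAmplitudes)
  modes <- matrix(0, 3 * m, k)
  for (j in seq_len(k)) {
    v <- stats::rnorm(3 * m)
    v <- v - Qrig %*% crossprod(Qrig, v)
    if (j > 1)
      v <- v - modes[, seq_len(j - 1), drop = FALSE] %*%
        crossprod(modes[, seq_len(j - 1), drop = FALSE], v)
    modes[, j] <- v / sqrt(sum(v^2))
  }

  scores <- matrix(0, nStructures, k)
  for (j in seq_len(k)) {
    s <- stats::rnorm(nStructures)
    if (j > 1)                              # orthogonalize against earlier
      s <- stats::resid(stats::lm(s ~ scores[, seq_len(j - 1), drop = FALSE]))
    scores[, j] <- (s - mean(s)) / stats::sd(s) * sdAmplitudes[j]
  }
  structures <- lapply(seq_len(nStructures), function(i) {
    v <- mu + as.numeric(modes %*% scores[i, ])
    matrix(v, ncol = 3, byrow = TRUE)
  })
  list(structures = structures, modes = modes, scores = scores,
       residueRange = as.integer(residueRange))
}
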