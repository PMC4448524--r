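#' @include geometry.R
NULL

## Cross-distance contact search between two heavy-atom coordinate sets.
## Returns which atoms of A are within cutoff of any atom of B and vice
## versa, plus the count under the requested convention.
.contactCount <- function(xA, xB, cutoff, convention = "atoms") {
  d2 <- outer(rowSums(xA^2), rowSums(xB^2), "+") - 2 * tcrossprod(xA, xB)
  hit <- d2 <= cutoff^2 + 1e-12
  inA <- rowSums(hit) > 0
  inB <- colSums(hit) > 0
  count <- if (convention == "pairs") sum(hit) else sum(inA) + sum(inB)
  list(count = as.integer(count), inA = inA, inB = inB)
}

#' Heavy-atom contact count between two chains
#'
#' A contact tallies the heavy (non-hydrogen) atoms of each chain lying
#' within \code{cutoff} of any heavy atom of the other chain; each atom is
#' counted once per side, so a single close atom pair contributes 2 under
#' the default convention. Inter-chain distances use the minimum-image
#' convention when the trajectory carries a box.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param chainA,chainB chain ids.
#' @param frame frame index (default 1).
#' @param cutoff contact cutoff, Angstrom (default 4).
#' @param convention \code{"atoms"} (count atoms, the default) or
#'   \code{"pairs"} (count atom pairs within cutoff), exposed for
#'   sensitivity checks.
#' @return Integer contact count.
#' @export
countContacts <- function(trajectory, chainA, chainB, frame = 1L,
                          cutoff = 4, convention = c("atoms", "pairs")) {
  convention <- match.arg(convention)
  topo <- topology(trajectory)
  a <- atoms(trajectory)
  hA <- chainAtomIndices(topo, chainA, heavyOnly = TRUE)
  hB <- chainAtomIndices(topo, chainB, heavyOnly = TRUE)
  if (!length(hA) || !length(hB))
    stop("both chains must contain at least one heavy atom")
  co <- coords(trajectory, frame = frame)
  xA <- co[hA, , drop = FALSE]; xB <- co[hB, , drop = FALSE]
  L <- boxEdge(trajectory)
  if (!is.null(L)) {
    comA <- centerOfMass(xA, a$mass[hA]); comB <- centerOfMass(xB, a$mass[hB])
    xB <- sweep(xB, 2, .minImageShift(comA, comB, L), "+")
  }
  .contactCount(xA, xB, cutoff, convention)$count
}

#' Chain-by-chain contact matrix for one frame
#'
#' @inheritParams countContacts
#' @return Symmetric integer matrix (chains x chains, zero diagonal) of
#'   heavy-atom contact counts.
#' @export
contactMatrix <- function(trajectory, frame = 1L, cutoff = 4) {
  ch <- topology(trajectory)@chains
  n <- length(ch)
  m <- matrix(0L, n, n, dimnames = list(ch, ch))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        countContacts(trajectory, ch[i], ch[j], frame = frame, cutoff = cutoff)
    }
  m
}

#' Per-residue contact-frequency profile
#'
#' For every frame and chain pair, each residue owning a counted contact
#' atom is incremented by the number of its counted atoms; profiles are
#' summed over frames (and pairs), then averaged across replicas when
#' several trajectories are supplied. Residue indices are pooled across
#' chains (all copies share the template numbering) unless \code{chainScope}
#' names a single chain.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of them
#'   (replicas).
#' @param pairs list of character(2) chain pairs; default all pairs.
#' @param cutoff contact cutoff, Angstrom.
#' @param chainScope \code{"all"} (default) or one chain id.
#' @return data.frame with columns \code{residue_index},
#'   \code{residue_name}, \code{count} (replica-averaged trajectory total)
#'   and \code{per_frame} (count normalized by frame count).
#' @export
residueContactProfile <- function(trajectories, pairs = NULL, cutoff = 4,
                                  chainScope = "all") {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  first <- trajectories[[1]]
  a1 <- atoms(first)
  ch1 <- topology(first)@chains[1]
  resIdx <- sort(unique(a1$resno[a1$chain == ch1]))
  resName <- a1$resid[a1$chain == ch1][match(resIdx,
                                             a1$resno[a1$chain == ch1])]
  profiles <- vapply(trajectories, function(tr) {
    topo <- topology(tr); a <- atoms(tr)
    chs <- topo@chains
    if (is.null(pairs)) {
      pp <- list()
      if (length(chs) > 1L)
        for (i in seq_len(length(chs) - 1L)) for (j in (i + 1L):length(chs))
          pp[[length(pp) + 1L]] <- c(chs[i], chs[j])
    } else pp <- pairs
    counts <- stats::setNames(numeric(length(resIdx)), resIdx)
    L <- boxEdge(tr); co <- coords(tr)
    for (pr in pp) {
      if (!all(pr %in% chs)) stop(sprintf("unknown chain id in pair %s-%s",
                                          pr[1], pr[2]))
      hA <- chainAtomIndices(topo, pr[1], heavyOnly = TRUE)
      hB <- chainAtomIndices(topo, pr[2], heavyOnly = TRUE)
      for (f in seq_len(nFrames(tr))) {
        xA <- matrix(co[f, hA, ], ncol = 3); xB <- matrix(co[f, hB, ], ncol = 3)
        if (!is.null(L)) {
          comA <- centerOfMass(xA, a$mass[hA])
          comB <- centerOfMass(xB, a$mass[hB])
          xB <- sweep(xB, 2, .minImageShift(comA, comB, L), "+")
        }
        cc <- .contactCount(xA, xB, cutoff)
        addSide <- function(idx, flag, chain) {
          if (chainScope != "all" && chain != chainScope) return()
          t <- table(a$resno[idx[flag]])
          counts[names(t)] <<- counts[names(t)] + as.numeric(t)
        }
        addSide(hA, cc$inA, pr[1]); addSide(hB, cc$inB, pr[2])
      }
    }
    counts
  }, numeric(length(resIdx)))
  profiles <- matrix(profiles, nrow = length(resIdx))
  avg <- rowMeans(profiles)
  nfr <- mean(vapply(trajectories, nFrames, 1L))
  data.frame(residue_index = resIdx, residue_name = resName,
             count = unname(avg), per_frame = unname(avg) / nfr)
}

#' Centered running average over residues
#'
#' Moving mean with an odd window, truncated (shorter window) at the
#' termini — the standard smoothing applied to per-residue contact profiles.
#'
#' @param counts numeric vector (or a profile data.frame with a
#'   \code{count} column).
#' @param window odd integer >= 1 (default 5 residues).
#' @return Numeric vector of the same length.
#' @export
runningResidueAverage <- function(counts, window = 5L) {
  if (is.data.frame(counts)) counts <- counts$count
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Compare two per-residue contact profiles
#'
#' Pearson correlation of the two profiles plus a peak-overlap score: the
#' Jaccard index of the residue sets lying strictly above each profile's own
#' 75th percentile.
#'
#' @param profileMD,profileRef numeric vectors of equal length (or profile
#'   data.frames with a \code{count} column).
#' @return list with \code{pearson_r} (NA with a warning for a
#'   zero-variance profile) and \code{peak_overlap} in [0, 1].
#' @export
compareProfiles <- function(profileMD, profileRef) {
  if (is.data.frame(profileMD)) profileMD <- profileMD$count
  if (is.data.frame(profileRef)) profileRef <- profileRef$count
  if (length(profileMD) != length(profileRef))
    stop("profiles must have equal length")
  r <- if (stats::sd(profileMD) == 0 || stats::sd(profileRef) == 0) {
    warning("zero-variance profile: Pearson correlation undefined")
    NA_real_
  } else stats::cor(profileMD, profileRef)
  peaks <- function(p) which(p > stats::quantile(p, 0.75))
  pA <- peaks(profileMD); pB <- peaks(profileRef)
  ov <- if (!length(pA) && !length(pB)) NA_real_
        else length(intersect(pA, pB)) / length(union(pA, pB))
  list(pearson_r = r, peak_overlap = ov)
}

#' Count interfacial (bridging) water molecules
#'
#' Counts water oxygens lying within \code{cutoff} of a heavy atom of chain
#' A \emph{and} of a heavy atom of chain B in one frame — the waters whose
#' expulsion accompanies the final approach of two binding surfaces.
#'
#' @inheritParams countContacts
#' @param waterResnames residue names identifying waters (default HOH, WAT,
#'   TIP3).
#' @return Integer count; 0 with a warning when the topology has no waters.
#' @export
interfacialWaterCount <- function(trajectory, chainA, chainB, frame = 1L,
                                  cutoff = 4,
                                  waterResnames = c("HOH", "WAT", "TIP3")) {
  topo <- topology(trajectory); a <- atoms(trajectory)
  wat <- which(a$resid %in% waterResnames &
               toupper(a$elesy) == "O" &
               !(a$chain %in% c(chainA, chainB)))
  if (!length(wat)) {
    wat <- which(a$resid %in% waterResnames & toupper(a$elesy) == "O")
    if (!length(wat)) {
      warning("no water molecules in topology")
      return(0L)
    }
  }
  co <- coords(trajectory, frame = frame)
  hA <- chainAtomIndices(topo, chainA, heavyOnly = TRUE)
  hB <- chainAtomIndices(topo, chainB, heavyOnly = TRUE)
  xW <- co[wat, , drop = FALSE]
  nearSide <- function(h) {
    d2 <- outer(rowSums(xW^2), rowSums(co[h, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xW, co[h, , drop = FALSE])
    rowSums(d2 <= cutoff^2 + 1e-12) > 0
  }
  sum(nearSide(hA) & nearSide(hB))
}
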