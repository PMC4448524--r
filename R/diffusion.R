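#' @include geometry.R
NULL

.msdCurve <- function(pos, lagIdx) {
  n <- nrow(pos)
  vapply(lagIdx, function(k) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Translational diffusion coefficient from mean-squared displacement
#'
#' Computes the time-origin-averaged MSD over a grid of lag times and fits
#' a straight line on the requested lag window; for 3D Brownian motion
#' MSD = 6 D tau, so D is the fitted slope over 6, converted from
#' Angstrom^2/ns to m^2/s (1 A^2/ns = 1e-11 m^2/s).
#'
#' Lags are analyzed up to \code{maxLagFraction} of the trajectory span —
#' beyond a few percent of the span the time-averaged MSD of a single
#' particle is dominated by sampling noise — and the default fit window
#' covers 10--50\% of that analyzed lag span, skipping the shortest
#' (transient-prone) lags and the tail. When several position series are
#' supplied (e.g. all copies of a multi-copy system) their MSD curves are
#' averaged before fitting: the ensemble MSD, with correspondingly smaller
#' statistical error. Input positions must be unwrapped (no periodic
#' jumps); see \code{\link{unwrapSeries}}.
#'
#' @param comSeries frames x 3 matrix of unwrapped positions (Angstrom), or
#'   a list of such matrices sharing \code{frameTimes}.
#' @param frameTimes frame times, ns, strictly increasing, uniform spacing.
#' @param fitWindow numeric(2) lag-time window (ns) for the linear fit;
#'   default 10--50\% of the analyzed lag span.
#' @param maxLagFraction fraction of the trajectory span up to which lags
#'   are analyzed (default 0.05).
#' @param maxLags cap on the number of lag points evaluated (default 500,
#'   evenly thinned).
#' @return A \linkS4class{DiffusionEstimate}; \code{D} is clamped to 0 with
#'   a warning when the fitted slope is negative.
#' @examples
#' set.seed(7)
#' steps <- matrix(rnorm(3000 * 3, sd = sqrt(2 * 3 * 0.1)), ncol = 3)
#' pos <- apply(steps, 2, cumsum)              # D = 3 A^2/ns = 3e-11 m^2/s
#' msdDiffusion(pos, seq(0, by = 0.1, length.out = 3000))
#' @export
msdDiffusion <- function(comSeries, frameTimes, fitWindow = NULL,
                         maxLagFraction = 0.05, maxLags = 500L) {
  serList <- if (is.list(comSeries)) lapply(comSeries, rbind)
             else list(rbind(comSeries))
  n <- nrow(serList[[1]])
  if (any(vapply(serList, nrow, 1L) != n))
    stop("all position series must share the frame count")
  if (length(frameTimes) != n)
    stop("frameTimes must have one entry per frame")
  if (n > 1L && any(diff(frameTimes) <= 0))
    stop("frameTimes must be strictly increasing")
  span <- frameTimes[n] - frameTimes[1]
  dt <- span / (n - 1)
  if (is.null(fitWindow)) fitWindow <- c(0.1, 0.5) * maxLagFraction * span

  maxLagIdx <- max(1L, min(n - 1L,
                           ceiling(max(fitWindow[2],
                                       maxLagFraction * span) / dt)))
  lagIdx <- unique(round(seq(1L, maxLagIdx,
                             length.out = min(maxLags, maxLagIdx))))
  msd <- rowMeans(vapply(serList, .msdCurve, numeric(length(lagIdx)),
                         lagIdx = lagIdx))
  lagT <- lagIdx * dt

  inWin <- lagT >= fitWindow[1] & lagT <= fitWindow[2]
  if (sum(inWin) < 10L)
    stop("fewer than 10 lag points inside the fit window")
  fit <- stats::lm(msd[inWin] ~ lagT[inWin])
  slope <- unname(stats::coef(fit)[2])      # A^2 / ns
  r2 <- summary(fit)$r.squared
  if (is.nan(r2)) r2 <- 0
  if (slope < 0) {
    warning("negative MSD slope; D clamped to 0")
    slope <- 0; r2 <- 0
  }
  new("DiffusionEstimate", D = slope / 6 * 1e-11,
      fitWindow = as.numeric(fitWindow),
      fitQuality = max(0, min(1, r2)),
      msd = data.frame(lag_ns = lagT, msd_A2 = msd))
}

.unwrappedComList <- function(trajectory, chains = NULL) {
  if (is.null(chains)) chains <- topology(trajectory)@chains
  L <- boxEdge(trajectory)
  lapply(stats::setNames(chains, chains), function(ch) {
    s <- comSeries(trajectory, ch)
    if (!is.null(L)) s <- unwrapSeries(s, L)
    s
  })
}

#' Per-chain diffusion coefficients of a trajectory
#'
#' Extracts each chain's center-of-mass series, unwraps periodic jumps, and
#' runs \code{\link{msdDiffusion}} chain by chain. The spread across chains
#' and replicas — not a single number — characterizes a system's
#' translational mobility.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param chains chain ids (default all).
#' @param ... passed to \code{\link{msdDiffusion}}.
#' @return Named list of \linkS4class{DiffusionEstimate}, one per chain.
#' @export
chainDiffusion <- function(trajectory, chains = NULL, ...) {
  lapply(.unwrappedComList(trajectory, chains), msdDiffusion,
         frameTimes = frameTimes(trajectory), ...)
}

#' Ensemble diffusion coefficient over all chains of a trajectory
#'
#' Averages the per-chain MSD curves before the linear fit (the ensemble
#' MSD), giving one estimate with smaller statistical error than any single
#' chain's.
#'
#' @inheritParams chainDiffusion
#' @return A single \linkS4class{DiffusionEstimate}.
#' @export
ensembleDiffusion <- function(trajectory, chains = NULL, ...) {
  msdDiffusion(unname(.unwrappedComList(trajectory, chains)),
               frameTimes = frameTimes(trajectory), ...)
}
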