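#' @include geometry.R
NULL

#' Detect binding and dissociation events in a pair series
#'
#' A bind event opens at the first frame of a run with
#' \code{n_contacts >= cOn} sustained for at least \code{persistence} ns.
#' Its completion is the first subsequent frame where the center-of-mass
#' distance comes within 10\% of the configured gyration diameter (the
#' compact-dimer anchor) or where the rolling-mean contact count changes by
#' less than 5\% across one persistence window (a contact plateau). An
#' unbind event opens when \code{n_contacts <= cOff} is sustained for
#' \code{persistence} ns after a bind. Events for a pair alternate
#' bind/unbind in time.
#'
#' @param pairSeries a \linkS4class{PairSeries} (needs \code{n_contacts}
#'   and, for distance-based completion, \code{com_distance_A}).
#' @param cOn contact threshold opening a bind (default 10 atoms).
#' @param cOff contact threshold opening an unbind (default 0).
#' @param persistence minimum duration a threshold must hold, ns
#'   (default 5).
#' @param gyrationDiam gyration diameter for the completion criterion,
#'   Angstrom; \code{NULL} disables the distance criterion.
#' @return data.frame with columns \code{kind} ("bind"/"unbind"),
#'   \code{chain_a}, \code{chain_b}, \code{onset_ns}, \code{completion_ns},
#'   \code{peak_contacts} (0 rows when nothing qualifies).
#' @export
detectEvents <- function(pairSeries, cOn = 10L, cOff = 0L, persistence = 5,
                         gyrationDiam = NULL) {
  s <- series(pairSeries)
  n <- nrow(s)
  if (n < 2L) stop("pair series needs >= 2 frames")
  tt <- s$time_ns
  if (any(diff(tt) <= 0)) stop("frame times must be strictly increasing")
  dt <- (tt[n] - tt[1]) / (n - 1)
  k <- max(1L, ceiling(persistence / dt))
  if (k > n) stop("persistence window longer than the trajectory")
  nc <- s$n_contacts

  ## sustained(i): predicate holds on every frame of [i, i+k-1]
  sustainedFrom <- function(pred) {
    ok <- logical(n)
    run <- 0L
    for (i in n:1) {                     # backward scan: run length ahead
      run <- if (pred[i]) run + 1L else 0L
      ok[i] <- run >= k
    }
    ok
  }
  bindOK  <- sustainedFrom(nc >= cOn)
  offOK   <- sustainedFrom(nc <= cOff)

  rollMean <- function(i) mean(nc[i:min(n, i + k - 1L)])

  events <- list()
  i <- 1L
  bound <- FALSE
  lastPeak <- NA_integer_
  while (i <= n) {
    if (!bound) {
      hit <- which(bindOK[i:n])[1]
      if (is.na(hit)) break
      onset <- i + hit - 1L
      ## completion: distance anchor or contact plateau
      comp <- NA_integer_
      for (j in onset:n) {
        if (!is.null(gyrationDiam) && !is.na(s$com_distance_A[j]) &&
            s$com_distance_A[j] <= 1.1 * gyrationDiam) { comp <- j; break }
        if (j > onset + k) {
          prev <- mean(nc[(j - k):(j - 1L)])
          if (prev > 0 && abs(rollMean(j) - prev) < 0.05 * prev) {
            comp <- j; break
          }
        }
      }
      if (is.na(comp)) comp <- n
      ## peak contacts over the bound stretch (until contacts drop to cOff)
      endB <- which(offOK[onset:n])[1]
      endB <- if (is.na(endB)) n else onset + endB - 1L
      lastPeak <- max(nc[onset:endB])
      events[[length(events) + 1L]] <- data.frame(
        kind = "bind", chain_a = pairSeries@chainPair[1],
        chain_b = pairSeries@chainPair[2], onset_ns = tt[onset],
        completion_ns = tt[comp], peak_contacts = as.integer(lastPeak))
      bound <- TRUE
      i <- onset + 1L
    } else {
      hit <- which(offOK[i:n])[1]
      if (is.na(hit)) break
      onset <- i + hit - 1L
      comp <- min(n, onset + k - 1L)
      events[[length(events) + 1L]] <- data.frame(
        kind = "unbind", chain_a = pairSeries@chainPair[1],
        chain_b = pairSeries@chainPair[2], onset_ns = tt[onset],
        completion_ns = tt[comp], peak_contacts = as.integer(lastPeak))
      bound <- FALSE
      i <- onset + 1L
    }
  }
  if (!length(events))
    return(data.frame(kind = character(), chain_a = character(),
                      chain_b = character(), onset_ns = numeric(),
                      completion_ns = numeric(),
                      peak_contacts = integer()))
  do.call(rbind, events)
}

#' Classify the oligomeric state of one frame from its contact matrix
#'
#' Chains are nodes; pairs with at least \code{threshold} contacts are
#' edges. Connected components are labeled by size; three-chain components
#' are split into \code{linear-trimer} (exactly 2 contacting pairs — a
#' middle chain bridging two ends) and \code{compact-trimer} (all 3 pairs in
#' contact). Output is invariant to chain relabeling up to the induced
#' permutation.
#'
#' @param contactMat square symmetric integer matrix with zero diagonal
#'   (chains x chains contact counts).
#' @param threshold minimum contact count forming an edge (default 1).
#' @return An object of class \code{OligomerState}: list with
#'   \code{partition} (list of chain-id vectors), \code{labels} (one per
#'   component) and \code{label} (canonical frame label, components sorted
#'   and joined with "+").
#' @export
classifyFrame <- function(contactMat, threshold = 1L) {
  if (nrow(contactMat) != ncol(contactMat) ||
      !isSymmetric(unname(contactMat)))
    stop("contact matrix must be square and symmetric")
  if (any(diag(contactMat) != 0)) stop("contact matrix diagonal must be 0")
  ch <- rownames(contactMat)
  if (is.null(ch)) ch <- as.character(seq_len(nrow(contactMat)))
  adj <- (contactMat >= threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  partition <- split(ch, comp$membership)
  labels <- vapply(seq_along(partition), function(k) {
    members <- which(comp$membership == k)
    size <- length(members)
    if (size == 1L) return("monomer")
    if (size == 2L) return("dimer")
    nEdges <- sum(adj[members, members]) / 2
    if (size == 3L) {
      if (nEdges == 2) return("linear-trimer")
      if (nEdges == 3) return("compact-trimer")
      return("trimer")                     # unreachable for connected comps
    }
    sprintf("%d-mer", size)
  }, character(1))
  structure(list(partition = unname(partition), labels = labels,
                 label = paste(sort(labels), collapse = "+")),
            class = "OligomerState")
}

#' @export
print.OligomerState <- function(x, ...) {
  cat("OligomerState:", x$label, "\n")
  for (k in seq_along(x$partition))
    cat(sprintf("  %s: {%s}\n", x$labels[k],
                paste(x$partition[[k]], collapse = ", ")))
  invisible(x)
}

#' Per-frame oligomer states and transition table
#'
#' Classifies every frame and tabulates transitions between consecutive
#' frame labels, making claims like "compact trimers never revert to linear
#' trimers" directly checkable.
#'
#' @param contactMats list of per-frame contact matrices (chains x chains),
#'   or a \linkS4class{Trajectory} (matrices computed at \code{cutoff}).
#' @param times frame times, ns (taken from the trajectory when one is
#'   supplied).
#' @param threshold contact-graph edge threshold (default 1).
#' @param cutoff contact cutoff when computing from a trajectory.
#' @return list with \code{states} (data.frame: frame, time_ns, label) and
#'   \code{transitions} (square count matrix over observed labels; empty —
#'   all zero — for a constant-state trajectory).
#' @export
stateTimeline <- function(contactMats, times = NULL, threshold = 1L,
                          cutoff = 4) {
  if (is(contactMats, "Trajectory")) {
    tr <- contactMats
    times <- frameTimes(tr)
    contactMats <- lapply(seq_len(nFrames(tr)), function(f)
      contactMatrix(tr, frame = f, cutoff = cutoff))
  }
  nf <- length(contactMats)
  if (is.null(times)) times <- seq_len(nf)
  labels <- vapply(contactMats, function(m)
    classifyFrame(m, threshold = threshold)$label, character(1))
  states <- data.frame(frame = seq_len(nf), time_ns = times, label = labels)
  lv <- unique(labels)
  trans <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  if (nf > 1L)
    for (f in 2:nf)
      if (labels[f] != labels[f - 1L])
        trans[labels[f - 1L], labels[f]] <-
          trans[labels[f - 1L], labels[f]] + 1L
  list(states = states, transitions = trans)
}
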