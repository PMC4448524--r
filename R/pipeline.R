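#' @include synthetic.R
NULL

#' Default run configuration
#'
#' The defaults carry the field-standard analysis constants: 4 Angstrom
#' heavy-atom contact cutoff, residues 2-70 for the PCA frame, 300 K, water
#' dielectric 78, 0.1 ns frame spacing, bind threshold 10 contact atoms
#' with 5 ns persistence. Every entry is overridable via the YAML config or
#' function arguments; the effective config is echoed verbatim into the
#' output directory.
#'
#' @return Nested named list of settings.
#' @export
defaultRunConfig <- function() {
  list(
    topology = NULL, trajectory = NULL, charges = NULL,
    box_edge = NULL, dt = 0.1, out = "encounter-out", seed = 1L,
    contact = list(cutoff = 4),
    events = list(c_on = 10L, c_off = 0L, persistence = 5),
    pca = list(residue_range = c(2L, 70L), frame = NULL,
               build_from_trajectory = FALSE, bins = 40L),
    temperature = 300, dielectric = 78,
    synthetic = list(n_copies = 3L, box_edge = 100, n_residues = 70L,
                     dipole_D = 250, D_trans = 3e-11, D_rot = 1e7,
                     dt = 0.1, n_steps = 100L, dipole_coupling = FALSE,
                     script = NULL)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; keys mirror \code{\link{defaultRunConfig}}.
#' @return Nested named list.
#' @export
readRunConfig <- function(path) {
  .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

## tiny FNV-1a over the deparsed config: a stable fingerprint for manifests
.configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.logLine <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

.writeManifest <- function(outDir, config) {
  jsonlite::write_json(
    list(package = "EncounterMD",
         version = as.character(utils::packageVersion("EncounterMD")),
         config_hash = .configHash(config), seed = config$seed),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
}

#' Generate a synthetic system and write its files
#'
#' Builds a \linkS4class{SyntheticSpec} from \code{config$synthetic}, runs
#' \code{\link{generateTrajectory}}, and writes the multi-model PDB
#' trajectory, a single-frame PQR with the constructed charges, the JSON
#' ground-truth sidecar (true diffusion coefficients, dipole, realized
#' event times, seed, spec echo) and a manifest into \code{config$out}.
#'
#' @param config nested list as from \code{\link{defaultRunConfig}} /
#'   \code{\link{readRunConfig}}.
#' @return The output directory, invisibly.
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  config <- .mergeConfig(defaultRunConfig(), config)
  outDir <- config$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon))
  sy <- config$synthetic
  .logLine(logCon, sprintf("simulate: seed %d, spec hash %s",
                           config$seed, .configHash(sy)))
  tpl <- makeTemplate(n_residues = sy$n_residues, dipole_target = sy$dipole_D)
  script <- if (!is.null(sy$script)) as.data.frame(sy$script) else NULL
  spec <- SyntheticSpec(nCopies = sy$n_copies, boxEdge = sy$box_edge,
                        template = tpl, DTrans = sy$D_trans,
                        DRot = sy$D_rot, dt = sy$dt, nSteps = sy$n_steps,
                        seed = config$seed, script = script,
                        dipoleCoupling = isTRUE(sy$dipole_coupling))
  res <- generateTrajectory(spec)
  t0 <- Sys.time()
  writeTrajectory(res$trajectory, file.path(outDir, "trajectory.pdb"))
  firstChain <- topology(res$trajectory)@chains[1]
  idx <- chainAtomIndices(topology(res$trajectory), firstChain)
  tplOut <- Trajectory(topology(tpl),
                       coords(res$trajectory, frame = 1)[idx, , drop = FALSE],
                       frameTimes = 0)
  writeTrajectory(tplOut, file.path(outDir, "template.pqr"), format = "pqr")
  jsonlite::write_json(res$groundTruth,
                       file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(outDir, config)
  .logLine(logCon, sprintf("simulate: wrote %d frames in %.1f s",
                           nFrames(res$trajectory),
                           as.numeric(Sys.time() - t0, units = "secs")))
  invisible(outDir)
}

#' Run the full analysis pipeline on a trajectory
#'
#' Stages (each logged with timing; a failing stage names itself in the
#' error): pair series for every chain pair (CSV each), per-residue contact
#' profile with running average, binding/dissociation event table,
#' oligomer-state timeline with transition counts, an optional PC landscape
#' (when \code{config$pca$frame} points to a serialized frame or
#' \code{config$pca$build_from_trajectory} is set), and a JSON summary with
#' per-chain diffusion coefficients, box concentration and per-pair event
#' counts.
#'
#' @param config nested list; either \code{config$trajectory} (+
#'   \code{topology} or \code{charges}) paths, or \code{config$input} as a
#'   ready \linkS4class{Trajectory}.
#' @return The output directory, invisibly.
#' @export
runAnalyze <- function(config = defaultRunConfig()) {
  config <- .mergeConfig(defaultRunConfig(), config)
  outDir <- config$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    .logLine(logCon, sprintf("%s: %.2f s", name,
                             as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  traj <- stage("read", {
    if (!is.null(config$input)) config$input
    else {
      topoSrc <- if (!is.null(config$topology)) config$topology
                 else config$trajectory
      if (is.null(topoSrc)) stop("no topology/trajectory input configured")
      topo <- topology(readStructure(topoSrc))
      if (!is.null(config$charges)) {
        ## per-copy charge template: recycle a single-chain PQR over all
        ## chains of a multi-copy topology
        q <- atoms(readStructure(config$charges, format = "pqr"))$charge
        a <- atoms(topo)
        if (length(q) == nrow(a)) a$charge <- q
        else if (nrow(a) %% length(q) == 0L)
          a$charge <- rep(q, nrow(a) %/% length(q))
        else stop("charge file atom count incompatible with topology")
        topo <- Topology(a)
      }
      readTrajectory(config$trajectory, topo, dt = config$dt,
                     boxEdge = config$box_edge)
    }
  })
  chs <- topology(traj)@chains
  cutoff <- config$contact$cutoff

  pairList <- list()
  if (length(chs) > 1L)
    for (i in seq_len(length(chs) - 1L)) for (j in (i + 1L):length(chs))
      pairList[[length(pairList) + 1L]] <- c(chs[i], chs[j])

  pairSeries <- stage("pair_series", lapply(pairList, function(pr) {
    ps <- computePairSeries(traj, pr, cutoff = cutoff)
    writeTable(as.data.frame(ps),
               file.path(outDir, sprintf("pair_%s_%s.csv", pr[1], pr[2])))
    ps
  }))

  stage("contact_profile", {
    prof <- residueContactProfile(traj, cutoff = cutoff)
    prof$running_avg <- runningResidueAverage(prof$count)
    writeTable(prof, file.path(outDir, "contact_profile.csv"))
  })

  gyr <- gyrationDiameter(
    coords(traj, frame = 1)[chainAtomIndices(topology(traj), chs[1]), ],
    atoms(traj)$mass[chainAtomIndices(topology(traj), chs[1])])

  eventTables <- stage("events", lapply(pairSeries, function(ps)
    detectEvents(ps, cOn = config$events$c_on, cOff = config$events$c_off,
                 persistence = config$events$persistence,
                 gyrationDiam = gyr)))
  allEvents <- do.call(rbind, eventTables)
  if (!is.null(allEvents) && nrow(allEvents))
    writeTable(allEvents, file.path(outDir, "events.csv"))

  timeline <- stage("timeline", stateTimeline(traj, cutoff = cutoff))
  writeTable(timeline$states, file.path(outDir, "state_timeline.csv"))

  if (!is.null(config$pca$frame) || isTRUE(config$pca$build_from_trajectory))
    stage("landscape", {
      frame <- if (!is.null(config$pca$frame)) readPCAFrame(config$pca$frame)
               else buildPCAFrame(traj, residueRange = config$pca$residue_range)
      pts <- pcaProject(frame, traj)
      grid <- logProbLandscape(pts, bins = config$pca$bins,
                               temperature = config$temperature)
      writeTable(landscapeTable(grid), file.path(outDir, "landscape.csv"))
    })

  summary <- stage("summary", {
    diff <- tryCatch(
      lapply(chainDiffusion(traj), function(d) d@D),
      error = function(e) NULL)
    evCounts <- lapply(eventTables, nrow)
    names(evCounts) <- vapply(pairList, paste, collapse = "-", "")
    list(
      n_chains = length(chs), n_frames = nFrames(traj),
      box_concentration_mM = if (!is.null(boxEdge(traj)))
        boxConcentration(length(chs), boxEdge(traj)) else NULL,
      D_per_chain_m2_s = diff, events_per_pair = evCounts,
      gyration_diameter_A = gyr)
  })
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(outDir, config)
  invisible(outDir)
}
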