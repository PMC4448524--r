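mkSeries <- function(contacts, dist = NULL, dt = 0.1) {
  n <- length(contacts)
  if (is.null(dist)) dist <- rep(50, n)
  new("PairSeries", chainPair = c("A", "B"),
      series = data.frame(time_ns = (seq_len(n) - 1) * dt,
                          com_distance_A = dist,
                          orientation_deg = NA_real_,
                          dipole_angle_deg = NA_real_,
                          n_contacts = contacts))
}

test_that("quiet and spiky contact series yield no events", {
  expect_equal(nrow(detectEvents(mkSeries(rep(0L, 200)), persistence = 2)), 0L)
  spiky <- rep(0L, 200); spiky[c(40, 90, 150)] <- 60L  # single-frame spikes
  expect_equal(nrow(detectEvents(mkSeries(spiky), persistence = 2)), 0L)
  expect_error(detectEvents(mkSeries(rep(0L, 20)), persistence = 100),
               "persistence")
})

test_that("bind and unbind events alternate with ordered times", {
  contacts <- c(rep(0L, 50), rep(80L, 100), rep(0L, 60), rep(90L, 80),
                rep(0L, 50))
  dist <- c(rep(60, 50), rep(20, 100), rep(55, 60), rep(21, 80), rep(60, 50))
  ev <- detectEvents(mkSeries(contacts, dist), persistence = 2,
                     gyrationDiam = 23.4)
  expect_equal(ev$kind, c("bind", "unbind", "bind", "unbind"))
  expect_true(all(diff(ev$onset_ns) > 0))
  expect_true(all(ev$completion_ns >= ev$onset_ns))
  expect_equal(ev$peak_contacts[1:2], c(80L, 80L))
  # bind onsets at the first sustained frame of each plateau
  expect_equal(ev$onset_ns[c(1, 3)], c(5.0, 21.0))
})

test_that("completion uses the gyration-diameter anchor when distance closes", {
  # contacts keep growing (no plateau), so the distance anchor decides
  contacts <- c(rep(0L, 30), as.integer(round(10 * 1.05^(0:119))))
  dist <- c(rep(60, 30), seq(40, 20, length.out = 120))
  ev <- detectEvents(mkSeries(contacts, dist), persistence = 2,
                     gyrationDiam = 23.4)
  expect_equal(ev$kind, "bind")
  # completion when distance first <= 1.1 * 23.4 = 25.74
  expectedFrame <- 30 + which(seq(40, 20, length.out = 120) <= 25.74)[1]
  expect_equal(ev$completion_ns, (expectedFrame - 1) * 0.1)
})

test_that("contact graphs classify monomers, dimers and both trimer shapes", {
  m0 <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  st <- classifyFrame(m0)
  expect_equal(st$labels, rep("monomer", 3))
  expect_equal(st$label, "monomer+monomer+monomer")

  m1 <- m0; m1["A", "B"] <- m1["B", "A"] <- 12L
  expect_equal(sort(classifyFrame(m1)$labels), c("dimer", "monomer"))

  m2 <- m1; m2["B", "C"] <- m2["C", "B"] <- 7L
  expect_equal(classifyFrame(m2)$label, "linear-trimer")

  m3 <- m2; m3["A", "C"] <- m3["C", "A"] <- 3L
  expect_equal(classifyFrame(m3)$label, "compact-trimer")

  # threshold gates which counts become edges
  expect_equal(classifyFrame(m3, threshold = 5L)$label, "linear-trimer")

  bad <- m1; bad["A", "B"] <- 99L
  expect_error(classifyFrame(bad), "symmetric")
})

test_that("classification is invariant under chain relabeling", {
  set.seed(17)
  for (i in 1:10) {
    n <- 4
    m <- matrix(0L, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (runif(1) < 0.4) m[a, b] <- m[b, a] <- sample(1:20, 1)
    dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
    perm <- sample(n)
    mp <- m[perm, perm]
    expect_equal(sort(classifyFrame(m)$labels),
                 sort(classifyFrame(mp)$labels))
  }
})

test_that("state timelines count transitions in order", {
  m0 <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  dimer <- m0; dimer["A", "B"] <- dimer["B", "A"] <- 20L
  compact <- dimer
  compact["B", "C"] <- compact["C", "B"] <- 15L
  compact["A", "C"] <- compact["C", "A"] <- 9L

  # constant-state trajectory: one label, no transitions
  tlConst <- stateTimeline(list(dimer, dimer, dimer))
  expect_equal(unique(tlConst$states$label), "dimer+monomer")
  expect_equal(sum(tlConst$transitions), 0L)

  # scripted monomers -> dimer -> compact trimer: exactly 2 transitions
  mats <- c(replicate(4, m0, simplify = FALSE),
            replicate(4, dimer, simplify = FALSE),
            replicate(4, compact, simplify = FALSE))
  tl <- stateTimeline(mats)
  expect_equal(sum(tl$transitions), 2L)
  expect_equal(tl$transitions["monomer+monomer+monomer", "dimer+monomer"], 1L)
  expect_equal(tl$transitions["dimer+monomer", "compact-trimer"], 1L)

  # bookkeeping: transition counts equal the number of label changes
  expect_equal(sum(tl$transitions),
               sum(tl$states$label[-1] != tl$states$label[-nrow(tl$states)]))
})

test_that("scripted synthetic binding is detected at the right time", {
  tpl <- makeTemplate(n_residues = 15L)
  script <- data.frame(chain_i = 1L, chain_j = 2L, bind_time_ns = 10,
                       approach_speed_A_ns = 8)
  spec <- SyntheticSpec(nCopies = 2L, boxEdge = 100, template = tpl,
                        nSteps = 350L, seed = 5L, script = script)
  res <- generateTrajectory(spec)
  ps <- computePairSeries(res$trajectory, c("A", "B"),
                          metrics = c("distance", "contacts"))
  ev <- detectEvents(ps, gyrationDiam = res$groundTruth$gyration_diameter_A)
  expect_equal(ev$kind, "bind")
  gt <- res$groundTruth$events$contact_time_ns
  expect_lt(abs(ev$onset_ns - gt), 5)            # within one persistence
  expect_gte(ev$peak_contacts, 10L)
})
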