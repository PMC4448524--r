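test_that("contact counting follows the heavy-atom, per-side convention", {
  # one heavy pair at 3.9 A: one atom on each side -> count 2
  expect_equal(countContacts(twoClusterTrajectory(3.9), "A", "B"), 2L)
  # nearest heavy pair at 4.1 A: outside the 4 A cutoff
  expect_equal(countContacts(twoClusterTrajectory(4.1), "A", "B"), 0L)
  # hydrogens 1 A apart while all heavy atoms are far: still 0
  expect_equal(countContacts(twoClusterTrajectory(20, hGap = 1), "A", "B"),
               0L)
  # pair convention exposed for sensitivity checks
  expect_equal(countContacts(twoClusterTrajectory(3.9), "A", "B",
                             convention = "pairs"), 1L)
})

test_that("contact counts are symmetric, cutoff-monotone and match brute force", {
  set.seed(23)
  for (rep in 1:5) {
    nA <- sample(10:40, 1); nB <- sample(10:40, 1)
    mk <- function(chain, n, center) {
      data.frame(chain = chain, resno = seq_len(n), resid = "ALA",
                 elety = "CA", elesy = "C", mass = 12.011, charge = 0)
    }
    topo <- Topology(rbind(mk("A", nA), mk("B", nB)))
    xA <- matrix(rnorm(nA * 3, 0, 4), ncol = 3)
    xB <- sweep(matrix(rnorm(nB * 3, 0, 4), ncol = 3), 2, c(6, 0, 0), "+")
    tr <- Trajectory(topo, rbind(xA, xB))
    prev <- 0L
    for (cut in c(2, 4, 6, 8)) {
      cnt <- countContacts(tr, "A", "B", cutoff = cut)
      expect_identical(cnt, countContacts(tr, "B", "A", cutoff = cut))
      expect_identical(cnt, as.integer(bruteContacts(xA, xB, cut)))
      expect_gte(cnt, prev)
      prev <- cnt
    }
  }
})

test_that("minimum imaging folds contacts across the box boundary", {
  # chains near opposite faces of the box touch through the boundary
  mk <- function(chain) data.frame(chain = chain, resno = 1, resid = "ALA",
                                   elety = "CA", elesy = "C", mass = 12.011,
                                   charge = 0)
  topo <- Topology(rbind(mk("A"), mk("B")))
  tr <- Trajectory(topo, rbind(c(1, 5, 5), c(99, 5, 5)), boxEdge = 100)
  expect_equal(countContacts(tr, "A", "B"), 2L)
  expect_equal(bruteContacts(rbind(c(1, 5, 5)), rbind(c(99, 5, 5)), 4, 100),
               2L)
})

test_that("residue profiles localize, add over frames, and average replicas", {
  tr <- twoClusterTrajectory(3.9)
  prof <- residueContactProfile(tr)
  # only residue 1 (the CA atoms) contacts; both sides pool to residue 1
  expect_equal(prof$count[prof$residue_index == 1], 2)
  expect_equal(prof$count[prof$residue_index == 2], 0)

  # duplicating frames doubles every count
  co2 <- array(NA_real_, dim = c(2, nAtoms(tr), 3))
  co2[1, , ] <- coords(tr, frame = 1); co2[2, , ] <- coords(tr, frame = 1)
  tr2 <- Trajectory(topology(tr), co2, frameTimes = c(0, 0.1))
  prof2 <- residueContactProfile(tr2)
  expect_equal(prof2$count, 2 * prof$count)
  # but the per-frame normalization is unchanged
  expect_equal(prof2$per_frame, prof$per_frame)

  # averaging identical replicas leaves the profile unchanged
  prof3 <- residueContactProfile(list(tr, tr, tr))
  expect_equal(prof3$count, prof$count)

  expect_error(residueContactProfile(tr, pairs = list(c("A", "Z"))),
               "unknown chain")
})

test_that("profile totals are consistent with the frame contact count", {
  set.seed(31)
  tpl <- makeTemplate(n_residues = 8)
  dim2 <- makeC2Dimer(tpl, comDistance = 0.9 * gyrationDiameter(
    coords(tpl, frame = 1), atoms(tpl)$mass))
  prof <- residueContactProfile(dim2)
  expect_equal(sum(prof$count), countContacts(dim2, "A", "B"))
})

test_that("running residue average smooths with truncated termini", {
  expect_equal(runningResidueAverage(rep(3, 10)), rep(3, 10))
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  out <- runningResidueAverage(imp, 5)
  expect_equal(out[3:7], rep(0.2, 5))
  expect_equal(out[c(1, 2, 8, 9)], rep(0, 4))
  expect_equal(runningResidueAverage(imp, 1), imp)
  expect_error(runningResidueAverage(imp, 4), "odd")
  # terminus: shorter window, plain mean of what exists
  expect_equal(runningResidueAverage(c(6, 0, 0), 5), c(2, 2, 2))
})

test_that("profile comparison reports correlation and peak overlap", {
  p <- c(0, 1, 5, 9, 2, 0, 0, 8, 1, 0)
  self <- compareProfiles(p, p)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$peak_overlap, 1)
  # linear ramp against its reversal: exact -1 correlation
  ramp <- 1:11
  expect_equal(compareProfiles(ramp, rev(ramp))$pearson_r, -1)
  # disjoint single peaks never overlap
  a <- c(9, 0, 0, 0, 0, 0); b <- c(0, 0, 0, 0, 0, 9)
  expect_equal(compareProfiles(a, b)$peak_overlap, 0)
  expect_warning(r <- compareProfiles(rep(2, 6), a)$pearson_r,
                 "zero-variance")
  expect_true(is.na(r))
  expect_error(compareProfiles(1:5, 1:6), "equal length")
})

test_that("interfacial waters are those bridging both chains", {
  base <- twoClusterTrajectory(8)
  expect_warning(n0 <- interfacialWaterCount(base, "A", "B"), "no water")
  expect_equal(n0, 0L)

  addWater <- function(tr, pos) {
    a <- atoms(tr)
    wat <- data.frame(chain = "W", resno = max(a$resno) + 1L, resid = "HOH",
                      elety = "OW", elesy = "O", heavy = TRUE, mass = 15.999,
                      charge = 0)
    Trajectory(Topology(rbind(a, wat)),
               rbind(coords(tr, frame = 1), pos))
  }
  # bridge water equidistant (< cutoff) from the facing CA atoms at +-4
  bridged <- addWater(base, c(0, 0, 0))
  expect_equal(interfacialWaterCount(bridged, "A", "B"), 1L)
  # water near A only
  oneSided <- addWater(base, c(-6, 0, 0))
  expect_equal(interfacialWaterCount(oneSided, "A", "B"), 0L)
})
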