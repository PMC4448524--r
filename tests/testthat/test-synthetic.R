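test_that("the template is deterministic, neutral, and dipole-calibrated", {
  tpl <- makeTemplate()
  a <- atoms(tpl)
  expect_equal(nrow(a), 70 * 9)
  expect_equal(sum(a$heavy), 560)
  expect_lt(abs(sum(a$charge)), 1e-6)
  mu <- dipoleMoment(coords(tpl, frame = 1), a$charge, a$mass)
  expect_equal(sqrt(sum(mu^2)), 250, tolerance = 0.01)

  tpl2 <- makeTemplate()
  expect_identical(coords(tpl), coords(tpl2))      # bit-identical
  expect_identical(atoms(tpl)$charge, atoms(tpl2)$charge)

  alt <- makeTemplate(n_residues = 20, dipole_target = 180)
  muAlt <- dipoleMoment(coords(alt, frame = 1), atoms(alt)$charge,
                        atoms(alt)$mass)
  expect_equal(sqrt(sum(muAlt^2)), 180, tolerance = 0.01)
  expect_error(makeTemplate(n_residues = 2), "3 residues")
})

test_that("initial placement respects the 30 A separation floor", {
  tpl <- makeTemplate(n_residues = 8)
  spec <- SyntheticSpec(nCopies = 3L, boxEdge = 100, template = tpl,
                        nSteps = 0L, seed = 2L)
  res <- generateTrajectory(spec)
  tr <- res$trajectory
  expect_equal(nFrames(tr), 1L)
  coms <- lapply(chains(tr), function(ch) comSeries(tr, ch)[1, ])
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(pbcDistance(coms[[i]], coms[[j]], 100), 30)
  # an over-packed box cannot satisfy the floor
  cramped <- SyntheticSpec(nCopies = 10L, boxEdge = 35, template = tpl,
                           nSteps = 0L, seed = 2L)
  expect_error(generateTrajectory(cramped), "30 A")
})

test_that("wrapped coordinates stay inside the box, molecules stay whole", {
  tpl <- makeTemplate(n_residues = 6)
  spec <- SyntheticSpec(nCopies = 2L, boxEdge = 60, template = tpl,
                        DTrans = 2e-10, nSteps = 300L, seed = 3L)
  tr <- generateTrajectory(spec)$trajectory
  # COM of every chain in every frame lies in [0, L)
  for (ch in chains(tr)) {
    s <- comSeries(tr, ch)
    expect_true(all(s >= -1e-9 & s < 60 + 1e-9))
    # chain never straddles the boundary: atom spread stays molecular
    idx <- chainAtomIndices(topology(tr), ch)
    for (f in c(1, 150, 301)) {
      x <- coords(tr, frame = f)[idx, ]
      expect_lt(max(apply(x, 2, function(v) diff(range(v)))), 30)
    }
  }
})

test_that("seeds make trajectories reproducible and distinct", {
  tpl <- makeTemplate(n_residues = 5)
  s1 <- SyntheticSpec(nCopies = 2L, boxEdge = 80, template = tpl,
                      nSteps = 20L, seed = 7L)
  r1 <- generateTrajectory(s1)
  r2 <- generateTrajectory(s1)
  expect_identical(coords(r1$trajectory), coords(r2$trajectory))
  s2 <- SyntheticSpec(nCopies = 2L, boxEdge = 80, template = tpl,
                      nSteps = 20L, seed = 8L)
  r3 <- generateTrajectory(s2)
  expect_false(identical(coords(r1$trajectory), coords(r3$trajectory)))
  expect_error(SyntheticSpec(nCopies = 2L, nSteps = 5L), "seed")
})

test_that("free-copy steps realize the specified translational diffusion", {
  tpl <- makeTemplate(n_residues = 5)
  spec <- SyntheticSpec(nCopies = 1L, boxEdge = 100, template = tpl,
                        DTrans = 3e-11, DRot = 0, nSteps = 4000L, seed = 1L)
  tr <- generateTrajectory(spec)$trajectory
  s <- unwrapSeries(comSeries(tr, "A"), 100)
  # per-axis step variance must be 2 D dt = 0.6 A^2 (D = 3 A^2/ns, dt 0.1)
  stepVar <- apply(diff(s), 2, var)
  expect_equal(unname(stepVar), rep(0.6, 3), tolerance = 0.1)
  # and the MSD estimator agrees within single-trajectory sampling error
  est <- ensembleDiffusion(tr, fitWindow = c(1, 5))
  expect_equal(est@D, 3e-11, tolerance = 0.3)
})

test_that("C2 dimers are exact two-fold symmetric pairs", {
  tpl <- makeTemplate(n_residues = 12)
  dim2 <- makeC2Dimer(tpl, comDistance = 28)
  a <- atoms(dim2)
  co <- coords(dim2, frame = 1)
  iA <- which(a$chain == "A"); iB <- which(a$chain == "B")
  expect_equal(orientationAngle(co[iA[a$heavy[iA]], ], co[iB[a$heavy[iB]], ],
                                a$mass[iA[a$heavy[iA]]]), 180)
  comA <- centerOfMass(co[iA, ], a$mass[iA])
  comB <- centerOfMass(co[iB, ], a$mass[iB])
  expect_equal(sqrt(sum((comA - comB)^2)), 28)
  # undoing the known 180-degree rotation superposes B exactly on A
  undone <- co[iB, ] %*% diag(c(-1, -1, 1))
  expect_equal(orientationAngle(co[iA, ], undone, a$mass[iA]), 0,
               tolerance = 1e-4)
})

test_that("mode ensembles carry their constructed covariance exactly", {
  ens <- makeModeEnsemble(makeTemplate(n_residues = 20), nStructures = 80,
                          sdAmplitudes = c(2, 1), seed = 12)
  expect_equal(apply(ens$scores, 2, sd), c(2, 1), tolerance = 1e-10)
  expect_equal(abs(cor(ens$scores[, 1], ens$scores[, 2])), 0,
               tolerance = 1e-10)
  expect_equal(crossprod(ens$modes), diag(2), tolerance = 1e-10)
})
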