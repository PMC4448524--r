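test_that("degenerate and rank-1 ensembles are handled explicitly", {
  tpl <- makeTemplate(n_residues = 10)
  ca <- coords(tpl, frame = 1)[atoms(tpl)$elety == "CA", ][2:9, ]
  expect_error(buildPCAFrame(list(ca, ca, ca)), "degenerate")
  expect_error(buildPCAFrame(list(ca)), ">= 2")
  # two distinct structures: rank-1 covariance, PC1 carries everything
  shifted <- ca + matrix(c(0.5, -0.2, 0.1), nrow(ca), 3, byrow = TRUE) *
    seq_len(nrow(ca))
  fr <- buildPCAFrame(list(ca, shifted))
  expect_equal(fr@varianceFractions[1], 1, tolerance = 1e-8)
})

test_that("two-mode synthetic ensembles recover their 80/20 variance split", {
  ens <- makeModeEnsemble(makeTemplate(), nStructures = 150,
                          sdAmplitudes = c(1, 0.5), seed = 9)
  fr <- buildPCAFrame(ens$structures, residueRange = ens$residueRange)
  expect_equal(fr@varianceFractions[1], 0.8, tolerance = 0.005)
  expect_equal(fr@varianceFractions[2], 0.2, tolerance = 0.005)
  expect_equal(sum(fr@varianceFractions), 1, tolerance = 1e-8)
  # eigenvalues sorted, eigenvectors orthonormal (validity-enforced)
  expect_true(all(diff(fr@eigenvalues) <= 1e-10))
})

test_that("projection respects orthonormality and rigid-transform invariance", {
  ens <- makeModeEnsemble(makeTemplate(n_residues = 30), nStructures = 60,
                          seed = 4)
  fr <- buildPCAFrame(ens$structures, residueRange = ens$residueRange)
  expect_equal(as.numeric(pcaProject(fr, fr@meanCoords)), c(0, 0),
               tolerance = 1e-8)
  # mean + c * eigenvector_1 projects to (c, 0)
  m <- nrow(fr@meanCoords)
  disp <- fr@meanCoords + matrix(3.2 * fr@eigenvectors[, 1], m, 3,
                                 byrow = TRUE)
  expect_equal(as.numeric(pcaProject(fr, disp)), c(3.2, 0), tolerance = 1e-6)
  # arbitrary rigid transform of the snapshot leaves scores unchanged
  set.seed(6)
  R <- randomRotation()
  moved <- sweep(ens$structures[[5]] %*% t(R), 2, c(30, -12, 7), "+")
  expect_equal(pcaProject(fr, moved), pcaProject(fr, ens$structures[[5]]),
               tolerance = 1e-6)
})

test_that("full-rank reconstruction reproduces aligned coordinates", {
  ens <- makeModeEnsemble(makeTemplate(n_residues = 12), nStructures = 40,
                          seed = 2)
  fr <- buildPCAFrame(ens$structures, residueRange = ens$residueRange)
  m <- nrow(fr@meanCoords)
  scores <- pcaProject(fr, ens$structures[[7]], nComponents = 3 * m)
  recon <- as.vector(t(fr@meanCoords)) + fr@eigenvectors %*% scores[1, ]
  aligned <- EncounterMD:::.superpose(ens$structures[[7]], fr@meanCoords)
  expect_equal(as.numeric(recon), as.vector(t(aligned)), tolerance = 1e-6)
})

test_that("log-probability landscapes are zero-based with kT checkpoints", {
  # all points in one bin: that bin is 0, everything else masked
  one <- logProbLandscape(matrix(c(rep(0.3, 20), rep(0.7, 20)), ncol = 2),
                          bins = 10)
  expect_equal(sum(!is.na(one@values)), 1L)
  expect_equal(min(one@values, na.rm = TRUE), 0)

  # two clusters with counts 1000 and 368 ~ N0/e: value ~ kB T
  pts <- rbind(matrix(0.01 * rnorm(2000), ncol = 2),
               sweep(matrix(0.01 * rnorm(736), ncol = 2), 2, c(5, 5), "+"))
  g <- logProbLandscape(pts, bins = 4, temperature = 300)
  v <- sort(unique(g@values[!is.na(g@values)]))
  expect_equal(v[1], 0)
  expect_equal(v[2], -0.0019872 * 300 * log(368 / 1000), tolerance = 1e-4)
  expect_equal(v[2], 0.596, tolerance = 0.01)   # one kB T at 300 K

  # doubling every count leaves values unchanged
  g2 <- logProbLandscape(rbind(pts, pts), bins = 4, temperature = 300)
  expect_equal(g2@values, g@values)
  expect_true(all(g@values[!is.na(g@values)] >= 0))
})

test_that("PCA frames serialize to text and back", {
  ens <- makeModeEnsemble(makeTemplate(n_residues = 12), nStructures = 30,
                          seed = 8)
  fr <- buildPCAFrame(ens$structures, residueRange = ens$residueRange)
  f <- tempfile(fileext = ".txt")
  writePCAFrame(fr, f)
  back <- readPCAFrame(f)
  expect_equal(back@meanCoords, fr@meanCoords, tolerance = 1e-12)
  expect_equal(back@eigenvalues, fr@eigenvalues, tolerance = 1e-12)
  expect_equal(back@eigenvectors, fr@eigenvectors, tolerance = 1e-12)
  expect_equal(pcaProject(back, ens$structures[[3]]),
               pcaProject(fr, ens$structures[[3]]), tolerance = 1e-9)
})
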