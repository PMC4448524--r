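test_that("center of mass is the mass-weighted mean position", {
  expect_equal(centerOfMass(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(centerOfMass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3)),
               c(3, 0, 0))
  expect_equal(centerOfMass(rbind(c(1, 2, 3))), c(1, 2, 3))
  expect_error(centerOfMass(matrix(numeric(), 0, 3)), "empty")
})

test_that("minimum-image distance honors the periodic box", {
  expect_equal(pbcDistance(c(5, 5, 5), c(95, 5, 5), 100), 10)
  expect_equal(pbcDistance(c(1, 2, 3), c(1, 2, 3), 100), 0)
  expect_equal(pbcDistance(c(10, 10, 10), c(40, 10, 10), 100), 30)
  # invariance under integer box shifts of either point
  set.seed(42)
  for (i in 1:20) {
    a <- runif(3, 0, 100); b <- runif(3, 0, 100)
    k <- sample(-3:3, 3, replace = TRUE)
    expect_equal(pbcDistance(a + 100 * k, b, 100), pbcDistance(a, b, 100))
    expect_lte(pbcDistance(a, b, 100), 100 * sqrt(3) / 2 + 1e-12)
  }
})

test_that("gyration diameter is twice the radius of gyration", {
  expect_equal(gyrationDiameter(rbind(c(1, 2, 3))), 0)
  expect_equal(gyrationDiameter(rbind(c(-1, 0, 0), c(1, 0, 0))), 2)
  # mass weighting: heavy atom pulls the COM, changing Rg accordingly
  co <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(gyrationDiameter(co, c(3, 1)), 2 * sqrt((3 * 1 + 1 * 9) / 4))
})

test_that("orientation angle equals the optimal-superposition rotation angle", {
  x <- coords(makeTemplate(n_residues = 6), frame = 1)
  expect_equal(orientationAngle(x, x), 0)
  expect_equal(orientationAngle(x, x %*% t(rotZ(90))), 90, tolerance = 1e-8)
  expect_equal(orientationAngle(x, x %*% t(rotZ(90))),
               quaternionAngle(rotZ(90)), tolerance = 1e-8)
  # C2-related copies: exactly 180 degrees
  expect_equal(orientationAngle(x, x %*% diag(c(-1, -1, 1))), 180)
  # random rotations vs the quaternion oracle; symmetry; translation invariance
  set.seed(11)
  for (i in 1:10) {
    R <- randomRotation()
    y <- x %*% t(R)
    expect_equal(orientationAngle(x, y), quaternionAngle(R), tolerance = 1e-6)
    expect_equal(orientationAngle(y, x), orientationAngle(x, y),
                 tolerance = 1e-6)
    shift <- matrix(runif(3, -50, 50), nrow(x), 3, byrow = TRUE)
    expect_equal(orientationAngle(x, y + shift), orientationAngle(x, y),
                 tolerance = 1e-6)
  }
  expect_error(orientationAngle(x[1:2, ], x[1:2, ]), ">= 3")
  lin <- cbind(1:5, 0, 0)
  expect_error(orientationAngle(lin, lin), "degenerate")
})

test_that("dipole moment converts e*A to Debye and is origin-free when neutral", {
  mu <- dipoleMoment(rbind(c(1, 0, 0), c(0, 0, 0)), c(1, -1))
  expect_equal(sqrt(sum(mu^2)), 4.80320, tolerance = 1e-5)
  expect_gt(mu[1], 0)
  # translation invariance for a neutral system
  co <- rbind(c(1, 2, 0), c(-1, 0, 3), c(0, -2, -3))
  q <- c(0.4, -0.3, -0.1)
  expect_equal(dipoleMoment(co, q),
               dipoleMoment(sweep(co, 2, c(17, -9, 4), "+"), q))
  expect_warning(z <- dipoleMoment(co, c(0, 0, 0)), "zero")
  expect_equal(z, c(0, 0, 0))
  expect_warning(dipoleMoment(co, c(1, 0, 0)), "net charge")
})

test_that("template dipole magnitude hits its constructed target", {
  tpl <- makeTemplate()
  a <- atoms(tpl)
  mu <- dipoleMoment(coords(tpl, frame = 1), a$charge, a$mass)
  expect_equal(sqrt(sum(mu^2)), 250, tolerance = 0.01)
})

test_that("vector angle covers parallel, antiparallel, orthogonal", {
  expect_equal(vectorAngle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(vectorAngle(c(1, 0, 0), c(-3, 0, 0)), 180)
  expect_equal(vectorAngle(c(1, 0, 0), c(0, 5, 0)), 90)
  expect_error(vectorAngle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("Brownian length follows sqrt(6 D t)", {
  expect_equal(round(brownianLength(2e-11, 1e-6)), 110)
  expect_equal(round(brownianLength(5e-11, 1e-6)), 173)
  expect_equal(brownianLength(3e-11, 0), 0)
  # squared length grows linearly in t with slope 6D, on a (D, t) grid
  for (D in c(1e-11, 3e-11, 8e-11)) for (t in c(1e-7, 5e-7, 2e-6)) {
    expect_equal(brownianLength(D, t)^2 * 1e-20, 6 * D * t, tolerance = 1e-12)
  }
})

test_that("box concentration matches n / (N_A V)", {
  expect_equal(boxConcentration(3, 100), 4.98, tolerance = 1e-3)
  expect_equal(boxConcentration(1, 100), 1.66, tolerance = 1e-3)
  expect_equal(boxConcentration(4, 200), boxConcentration(4, 100) / 8)
})

test_that("pair series combine distance, angles and contacts consistently", {
  tr <- twoClusterTrajectory(gap = 3.5, boxEdge = 50)
  ps <- computePairSeries(tr, c("A", "B"),
                          metrics = c("distance", "orientation", "contacts"))
  s <- series(ps)
  expect_equal(s$n_contacts, 2L)
  expect_gt(s$com_distance_A, 0)
  expect_true(is.na(s$dipole_angle_deg))
  # zero charges: asking for dipoles warns and leaves the column NA
  expect_warning(ps2 <- computePairSeries(tr, c("A", "B")), "charges")
  expect_true(all(is.na(series(ps2)$dipole_angle_deg)))
})
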