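test_that("hull-volume mass regression evaluates the power law", {
  expect_equal(estimateMassFromHull(0.5, a = 1000, b = 1), 500)
  expect_equal(estimateMassFromHull(0, a = 50, b = 0.9), 0)
  expect_equal(estimateMassFromHull(2, a = 10, b = 0.5), 10 * sqrt(2))
  expect_error(estimateMassFromHull(-1, a = 10, b = 1), "negative")
  expect_error(estimateMassFromHull(1, a = -5, b = 1), "positive")
})

test_that("polygon inertia matches closed forms and scales with mass", {
  w <- 0.4; h <- 1.2; m <- 7
  r <- computePlanarInertia(rectOutline(-w / 2, w / 2, -h / 2, h / 2), m)
  expect_equal(r$inertiaZz, m * (w^2 + h^2) / 12, tolerance = 1e-12)
  expect_equal(r$com, c(0, 0))

  u <- computePlanarInertia(rectOutline(0, 1, 0, 1), 12)
  expect_equal(u$inertiaZz, 2)
  expect_equal(u$com, c(0.5, 0.5))

  dbl <- computePlanarInertia(rectOutline(0, 1, 0, 1), 24)
  expect_equal(dbl$inertiaZz, 2 * u$inertiaZz)
  expect_error(computePlanarInertia(rectOutline(0, 1, 0, 1), 0), "positive")
})

test_that("limb mass allocation conserves total mass", {
  out <- assignLimbMassFractions(
    100, c(thigh_l = 0.1, shank_l = 0.05, thigh_r = 0.1, shank_r = 0.05))
  expect_equal(unname(out[c("thigh_l", "shank_l", "thigh_r", "shank_r")]),
               c(10, 5, 10, 5))
  expect_equal(unname(out[["trunk"]]), 70)
  expect_equal(sum(out), 100)

  allTrunk <- assignLimbMassFractions(7206.7, c(thigh = 0))
  expect_equal(unname(allTrunk[["trunk"]]), 7206.7)
  expect_error(assignLimbMassFractions(10, c(a = 0.6, b = 0.5)), "above 1")
  expect_error(assignLimbMassFractions(10, c(a = -0.1)), "negative")
})

test_that("muscle mass allocation splits groups equally and conserves totals", {
  groups <- list(ext = c("m1", "m2"), flex = c("m3"))
  mm <- assignMuscleMasses(100, 0.5, c(ext = 0.5, flex = 0.5), groups)
  expect_equal(unname(mm[c("m1", "m2")]), c(12.5, 12.5))
  expect_equal(unname(mm[["m3"]]), 25)
  expect_equal(sum(mm), 0.5 * 100)

  z <- assignMuscleMasses(100, 0, c(ext = 0.5, flex = 0.5), groups)
  expect_true(all(z == 0))
  expect_error(assignMuscleMasses(100, 0.5, c(ext = 1), list(ext = NULL)),
               "no muscles")
  expect_error(assignMuscleMasses(100, 0.5, c(ext = 0.7, flex = 0.7),
                                  groups), "sum to 1")
})

test_that("fibre/tendon tuning recovers the closed-form length sweep", {
  m <- makeArmRig()
  # independent oracle: law-of-cosines MTU length over the joint range
  th <- seq(-1, 1, length.out = 2001)
  Lref <- armRigLength(th)
  dLref <- max(Lref) - min(Lref)
  tuned <- tuneFibreTendonLengths(m, "mus", fibreFraction = 1)
  expect_equal(tuned$deltaL, dLref, tolerance = 1e-3)
  expect_equal(tuned$fibreLength, dLref, tolerance = 1e-3)

  half <- tuneFibreTendonLengths(m, "mus", fibreFraction = 0.5)
  expect_equal(half$fibreLength, tuned$fibreLength / 2)
  expect_equal(half$tendonSlackLength, half$midLength - half$fibreLength)
  expect_equal(half$midLength, armRigLength(0), tolerance = 1e-12)

  zero <- tuneFibreTendonLengths(m, "mus", fibreFraction = 0)
  expect_equal(zero$fibreLength, 0)
  expect_equal(zero$tendonSlackLength, zero$midLength)

  # doubling the geometry doubles the sweep
  big <- makeArmRig(basePoint = c(0.2, 0), armPoint = c(0, -0.4))
  tunedBig <- tuneFibreTendonLengths(big, "mus", fibreFraction = 1)
  expect_equal(tunedBig$fibreLength, 2 * tuned$fibreLength,
               tolerance = 1e-3)
})

test_that("model validation reports violations as data", {
  expect_identical(validateModel(makeToyBiped()), character(0))
  expect_identical(validateModel(makePendulum()), character(0))
  expect_identical(validateModel(makeDropTest()), character(0))

  m <- makeToyBiped()
  m$segments[["shank_l"]]$mass <- -2
  v <- validateModel(m)
  expect_true(any(grepl("shank_l.*mass", v)))

  # joint cycle: two segments each the child of the other
  a <- segment("a", rectOutline(-0.1, 0.1, -0.1, 0.1), 1, 0.1)
  b <- segment("b", rectOutline(-0.1, 0.1, -0.1, 0.1), 1, 0.1)
  cyc <- bipedModel(list(a, b),
                    list(hingeJoint("a", "b", c(0, 0), c(0, 0)),
                         hingeJoint("b", "a", c(0, 0), c(0, 0))))
  v2 <- validateModel(cyc)
  expect_true(any(grepl("root", v2)))

  # orphan segment (unreachable from the root)
  c_ <- segment("c", rectOutline(-0.1, 0.1, -0.1, 0.1), 1, 0.1)
  orph <- bipedModel(list(a, b, c_),
                     list(hingeJoint("a", "b", c(0, 0), c(0, 0))))
  expect_true(any(grepl("root", validateModel(orph))))
})

test_that("muscle fmax derives from mass via specific tension", {
  expect_equal(muscleFmaxFromMass(1056, 1, specificTension = 3e5), 3e5)
  expect_equal(muscleFmaxFromMass(2, 0.1), 3e5 * 2 / (1056 * 0.1))
  expect_error(muscleFmaxFromMass(1, 0), "positive")
})
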