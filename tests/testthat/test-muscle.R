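test_that("MTU length is the world-frame polyline length", {
  m <- makeArmRig(basePoint = c(0.1, 0), armPoint = c(0, -0.2))
  pose <- referencePose(m)
  expect_equal(mtuLength(m, "mus", pose), armRigLength(0), tolerance = 1e-12)
  pose$angles[["arm"]] <- 0.6
  expect_equal(mtuLength(m, "mus", pose), armRigLength(0.6),
               tolerance = 1e-12)
  # collinear via-point leaves the end-to-end length unchanged
  m2 <- makeArmRig()
  mus <- m2$muscles[["mus"]]
  mid <- c((0.1 + 0) / 2, (0 - 0.2) / 2)   # midpoint on the base segment
  mus$path <- data.frame(segment = c("base", "base", "arm"),
                         x = c(0.1, mid[1], 0),
                         y = c(0, mid[2], -0.2))
  m2$muscles[["mus"]] <- mus
  expect_equal(mtuLength(m2, "mus", referencePose(m2)), armRigLength(0),
               tolerance = 1e-12)
  # rigid translation of the whole model leaves lengths unchanged
  pose2 <- referencePose(m)
  pose2$root <- c(5, -3, 0)
  expect_equal(mtuLength(m, "mus", pose2), mtuLength(m, "mus"),
               tolerance = 1e-12)
})

test_that("moment arm equals the perpendicular distance to the muscle line", {
  A <- c(0.1, 0.02); B <- c(0.03, -0.25)
  m <- makeArmRig(basePoint = A, armPoint = B)
  pose <- referencePose(m)
  arm <- momentArm(m, "mus", "arm", pose)
  # oracle: |cross(A - O, B - A)| / |B - A| with O the joint at the origin
  d <- abs(A[1] * (B[2] - A[2]) - A[2] * (B[1] - A[1])) /
    sqrt(sum((B - A)^2))
  expect_equal(abs(arm), d, tolerance = 1e-4)

  # torque balance: Q_theta = T * momentArm must equal cross(B, F)
  Tt <- 123
  u <- (A - B) / sqrt(sum((A - B)^2))       # pull direction at insertion
  tau <- B[1] * (Tt * u[2]) - B[2] * (Tt * u[1])
  expect_equal(Tt * arm, tau, tolerance = 1e-6 * abs(tau))

  # path through the joint centre gives a zero arm
  m0 <- makeArmRig(basePoint = c(0.1, 0), armPoint = c(0, 0))
  expect_equal(momentArm(m0, "mus", "arm"), 0, tolerance = 1e-8)

  # reversing the path direction leaves the magnitude unchanged
  mr <- makeArmRig(basePoint = A, armPoint = B)
  mus <- mr$muscles[["mus"]]
  mus$path <- mus$path[2:1, ]
  mr$muscles[["mus"]] <- mus
  expect_equal(abs(momentArm(mr, "mus", "arm")), abs(arm),
               tolerance = 1e-10)

  expect_error(momentArm(makeArmRig(), "mus", "nosuch"), "no joint")
})

test_that("Hill curves are bounded with the canonical anchors", {
  l <- seq(0, 2.5, by = 0.01)
  expect_true(all(forceLengthCurve(l) >= 0 & forceLengthCurve(l) <= 1))
  expect_equal(forceLengthCurve(1), 1)
  v <- seq(-2, 2, by = 0.01)
  fv <- forceVelocityCurve(v)
  expect_true(all(fv >= 0 & fv <= 1.8))
  expect_equal(forceVelocityCurve(0), 1)
  expect_equal(forceVelocityCurve(-1), 0)
  expect_true(all(passiveForceCurve(l) >= 0))
  expect_equal(passiveForceCurve(1), 0)
})

test_that("series-elastic MTU force honours the contract anchors", {
  mus <- muscleTendonUnit(
    "m", data.frame(segment = c("a", "b"), x = c(0, 0), y = c(0, -0.3)),
    fmax = 1000, fibreLength = 0.1, tendonSlackLength = 0.2)
  # slack everywhere: no force
  expect_equal(mtuForce(mus, 0, 0.2 + 0.1), 0, tolerance = 1e-9)
  # taut isometric equilibrium at optimal fibre length carries fmax:
  # tendon strain at fmax is 1/tendonStiffness
  L <- 0.1 + 0.2 * (1 + 1 / 30)
  expect_equal(mtuForce(mus, 1, L), 1000, tolerance = 1e-6)
  # shortening at the maximum contraction velocity kills the active
  # force: only the passive contribution remains, so full and zero
  # activation coincide
  fFast <- mtuForce(mus, 1, L, mtuVelocity = -10 * 0.1)
  fPassive <- mtuForce(mus, 0, L)
  expect_equal(fFast, fPassive, tolerance = 1e-6)
  expect_lt(fFast, 0.02 * 1000)
  expect_error(mtuForce(mus, 2, L), "activation")
  expect_error(mtuForce(mus, NaN, L), "finite")
})

test_that("activation dynamics relax exponentially and stay bounded", {
  expect_equal(activationUpdate(0.4, 0.4, 0.01), 0.4)
  # one time constant after a 0 -> 1 step
  expect_equal(activationUpdate(1, 0, dt = 0.05, timeConstant = 0.05),
               1 - exp(-1), tolerance = 1e-12)
  # dt -> 0 limit: no change
  expect_equal(activationUpdate(1, 0.2, dt = 1e-12), 0.2, tolerance = 1e-6)
  a <- 0
  for (i in 1:1000) a <- activationUpdate(1, a, 0.01)
  expect_lte(a, 1)
  expect_error(activationUpdate(1.2, 0, 0.01), "excitation")
})

test_that("internal muscle forces exert no net force or torque on the model", {
  # a muscle spanning two free bodies: total linear momentum and angular
  # momentum about the origin must evolve under gravity alone
  m <- makeToyBiped()
  ctrl <- cyclicController(
    0.5, matrix(0.8, length(m$muscles), 1,
                dimnames = list(names(m$muscles), NULL)))
  mNoContact <- m
  mNoContact$contacts <- list()           # free flight: gravity + muscles
  cfg <- simConfig(timestep = 1e-4, duration = 0.25,
                   recordInterval = 1e-4, fallHeightFraction = NA)
  tr <- runSimulation(mNoContact, ctrl, cfg)
  v <- tr$comVel[, 2]
  g <- 9.81
  # COM vertical velocity is exactly ballistic despite large muscle forces
  expect_equal(v, v[1] - g * tr$time, tolerance = 1e-4)
  expect_equal(tr$comVel[, 1], rep(tr$comVel[1, 1], length(v)),
               tolerance = 1e-4)
})
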