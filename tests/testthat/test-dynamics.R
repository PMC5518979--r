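test_that("contact spheres act as one-sided spring-dampers with bounded friction", {
  sp <- contactSphere("pes", c(0, 0), radius = 0.1, stiffness = 1e6,
                      damping = 500, frictionMu = 0.8)
  # sphere above the ground: no force
  expect_equal(contactForce(sp, center = c(0, 0.2)), c(0, 0))
  # 1 mm penetration, no velocity: pure spring
  f <- contactForce(sp, center = c(0, 0.099))
  expect_equal(f[2], 1e6 * 0.001)
  expect_equal(f[1], 0)
  # fast separation: spring + damper would be tensile -> clamped to zero
  f2 <- contactForce(sp, center = c(0, 0.099), centerVel = c(0, 10))
  expect_equal(f2, c(0, 0))
  # sliding: tangential force saturates at mu * N and opposes slip
  f3 <- contactForce(sp, center = c(0, 0.099), centerVel = c(1, 0))
  expect_equal(f3[1], -0.8 * f3[2])
  f4 <- contactForce(sp, center = c(0, 0.099), centerVel = c(-1, 0))
  expect_equal(f4[1], 0.8 * f4[2])
})

test_that("segment splitting conserves mass, COM and inertia", {
  m <- makeToyBiped()
  seg <- m$segments[["thigh_l"]]
  sp <- splitSegmentForLoad(m, "thigh_l", cutFraction = 0.4)
  a <- sp$segments[["thigh_l_prox"]]
  b <- sp$segments[["thigh_l_dist"]]
  expect_equal(a$mass + b$mass, seg$mass, tolerance = 1e-12)
  comAB <- (a$mass * a$comLocal + b$mass * b$comLocal) / seg$mass
  expect_equal(comAB, seg$comLocal, tolerance = 1e-9)
  Irec <- a$inertiaZz + a$mass * sum((a$comLocal - comAB)^2) +
    b$inertiaZz + b$mass * sum((b$comLocal - comAB)^2)
  expect_equal(Irec, seg$inertiaZz, tolerance = 1e-9)
  expect_error(splitSegmentForLoad(m, "nosuch"), "unknown segment")
  expect_error(splitSegmentForLoad(m, "thigh_l", 1.2), "between 0 and 1")

  # uniform thin bar halves: each m/2 with inertia ~ (m/2) L^2 / 48
  p <- splitSegmentForLoad(makePendulum(length = 1, mass = 1, width = 1e-4),
                           "bar", 0.5)
  h1 <- p$segments[["bar_prox"]]
  expect_equal(h1$mass, 0.5)
  expect_equal(h1$inertiaZz, 0.5 * 1^2 / 48, tolerance = 1e-6)
})

test_that("split and unsplit passive models follow identical trajectories", {
  p1 <- makePendulum()
  p2 <- splitSegmentForLoad(makePendulum(), "bar", 0.5)
  pose1 <- referencePose(p1); pose1$angles[["bar"]] <- 0.8
  pose2 <- referencePose(p2); pose2$angles[["bar_prox"]] <- 0.8
  cfg <- simConfig(timestep = 1e-4, duration = 2, fallHeightFraction = NA)
  t1 <- runSimulation(p1, config = cfg, pose = pose1)
  t2 <- runSimulation(p2, config = cfg, pose = pose2)
  expect_lt(max(abs(t1$com - t2$com)), 1e-6)
})

test_that("a free body falls with v = g t", {
  ball <- segment("ball", rectOutline(-0.1, 0.1, -0.1, 0.1), mass = 2,
                  length = 0.1)
  m <- bipedModel(list(ball), list())
  pose <- referencePose(m); pose$root <- c(0, 100, 0)
  tr <- runSimulation(m, config = simConfig(timestep = 1e-4, duration = 1,
                                            fallHeightFraction = NA),
                      pose = pose)
  v <- -tr$comVel[-1, 2]
  expect_equal(v, 9.81 * tr$time[-1], tolerance = 1e-6)
})

test_that("small-amplitude pendulum period matches the closed form", {
  m <- makePendulum(length = 1, mass = 1)
  pose <- referencePose(m); pose$angles[["bar"]] <- 0.05
  tr <- runSimulation(m, config = simConfig(timestep = 1e-4, duration = 10,
                                            fallHeightFraction = NA),
                      pose = pose)
  ang <- tr$q[, 1]
  zc <- which(diff(sign(ang)) != 0)
  period <- 2 * mean(diff(tr$time[zc]))
  # uniform bar about its end: I = m L^2 / 3, COM at L/2
  Texp <- 2 * pi * sqrt((1 / 3) / (9.81 * 0.5))
  expect_equal(period, Texp, tolerance = 0.01)
})

test_that("passive frictionless energy drift stays below 0.1% over 10 s", {
  m <- makePendulum(double = TRUE)
  pose <- referencePose(m)
  pose$angles[["bar"]] <- 0.9
  pose$angles[["bar2"]] <- -0.4
  tr <- runSimulation(m, config = simConfig(timestep = 5e-5, duration = 10,
                                            fallHeightFraction = NA),
                      pose = pose)
  E <- tr$kineticEnergy + tr$potentialEnergy
  # drift relative to the oscillation energy (max kinetic energy reached)
  expect_lt((max(E) - min(E)) / max(tr$kineticEnergy), 1e-3)
})

test_that("linear momentum follows the external impulse", {
  # muscle and joint forces are internal: in free flight the COM is
  # exactly ballistic even under strong asymmetric activation
  m <- makeToyBiped()
  set.seed(11)
  lv <- matrix(stats::runif(length(m$muscles) * 4, 0.2, 1),
               length(m$muscles), 4,
               dimnames = list(names(m$muscles), NULL))
  ctrl <- cyclicController(0.4, lv)
  mFree <- m
  mFree$contacts <- list()
  cfg <- simConfig(timestep = 1e-4, duration = 0.3, recordInterval = 0.01,
                   fallHeightFraction = NA)
  tr <- runSimulation(mFree, ctrl, cfg)
  expect_equal(tr$comVel[, 2], tr$comVel[1, 2] - 9.81 * tr$time,
               tolerance = 1e-4)
  expect_equal(tr$comVel[, 1], rep(tr$comVel[1, 1], length(tr$time)),
               tolerance = 1e-4)

  # with ground contact, the impulse of (gravity + contact) accounts for
  # the vertical momentum change step by step
  d <- makeDropTest()
  pose <- referencePose(d); pose$root <- c(0, 0.15, 0)
  cfg2 <- simConfig(timestep = 1e-4, duration = 0.5, recordInterval = 1e-4,
                    fallHeightFraction = NA)
  trd <- runSimulation(d, config = cfg2, pose = pose)
  n <- length(trd$time)
  Fy <- trd$contactForce[, 2] - 1 * 9.81
  impulse <- cumsum(Fy[-n]) * 1e-4
  dp <- 1 * (trd$comVel[-1, 2] - trd$comVel[1, 2])
  expect_equal(dp, impulse, tolerance = 1e-6)
})

test_that("contact normal force is never tensile during a bounce", {
  d <- makeDropTest(damping = 10)
  pose <- referencePose(d); pose$root <- c(0, 0.3, 0)
  tr <- runSimulation(d, config = simConfig(timestep = 1e-4, duration = 1,
                                            recordInterval = 1e-3,
                                            fallHeightFraction = NA),
                      pose = pose)
  expect_true(all(tr$contactForce[, 2] >= 0))
})

test_that("hinge anchors coincide exactly along a simulated trajectory", {
  m <- makeToyBiped()
  tr <- runSimulation(m, NULL, simConfig(timestep = 5e-4, duration = 0.5,
                                         fallHeightFraction = NA))
  comp <- bipedsim:::compileModel(m, simConfig())
  hinges <- Filter(function(j) j$type == "hinge", m$joints)
  for (i in c(1, nrow(tr$q))) {
    pose <- referencePose(m)
    pose$root <- tr$q[i, 1:3]
    for (j in hinges) {
      b <- comp$idx[[j$child]] + 1L
      d <- comp$body$dof[b]
      pose$angles[[j$child]] <- tr$q[i, d + 1L]
    }
    fk <- forwardKinematics(m, pose)
    for (j in hinges) {
      pa <- bipedsim:::worldPoint(fk, j$parent, j$anchorParent)
      pc <- bipedsim:::worldPoint(fk, j$child, j$anchorChild)
      expect_lt(sqrt(sum((pa - pc)^2)), 1e-8)
    }
  }
})

test_that("static internal loads at a mid-shaft cut match beam statics", {
  # horizontal cantilever: shear m g, bending moment m g d at the cut
  mc <- splitSegmentForLoad(makePendulum(length = 2, mass = 4), "bar", 0.5)
  pose <- referencePose(mc)
  pose$angles[["bar_prox"]] <- pi / 2
  il <- measureInternalLoad(mc, "bar", pose)
  mHalf <- 2; d <- 0.5
  expect_equal(abs(il$shear), mHalf * 9.81, tolerance = 1e-6)
  expect_equal(abs(il$moment), mHalf * 9.81 * d, tolerance = 1e-6)
  expect_equal(il$axial, 0, tolerance = 1e-9)

  # vertical hanging column: pure axial tension m g below the cut
  il2 <- measureInternalLoad(mc, "bar", referencePose(mc))
  expect_equal(il2$axial, mHalf * 9.81, tolerance = 1e-6)
  expect_equal(il2$shear, 0, tolerance = 1e-9)
  expect_equal(il2$moment, 0, tolerance = 1e-9)

  # zero gravity at rest: all components vanish
  mg0 <- mc
  mg0$gravity <- c(0, 0)
  il3 <- measureInternalLoad(mg0, "bar", pose)
  expect_equal(abs(il3$axial) + abs(il3$shear) + abs(il3$moment), 0)

  expect_error(measureInternalLoad(mc, "base", pose), "monitored")
})

test_that("simulations are bit-reproducible and terminate as configured", {
  m <- attachStressMonitors(makeToyBiped())
  lv <- matrix(0.5, length(m$muscles), 1,
               dimnames = list(names(m$muscles), NULL))
  ctrl <- cyclicController(0.5, lv)
  cfg <- simConfig(timestep = 5e-4, duration = 1)
  t1 <- runSimulation(m, ctrl, cfg)
  t2 <- runSimulation(m, ctrl, cfg)
  expect_identical(t1$com, t2$com)
  expect_identical(t1$stressFiltered, t2$stressFiltered)
  expect_identical(t1$termination, t2$termination)

  # zero stress limit: fail at the first monitored step
  cfg0 <- simConfig(timestep = 5e-4, duration = 1, stressLimit = 0)
  t0 <- runSimulation(m, NULL, cfg0)
  expect_equal(t0$termination$cause, "stress_fail")
  expect_equal(t0$termination$time, 0)

  # drop the ball: settles to the static penetration m g / k
  d <- makeDropTest()
  trd <- runSimulation(d, config = simConfig(timestep = 1e-4, duration = 3,
                                             fallHeightFraction = NA))
  pen <- 0.1 - trd$com[nrow(trd$com), 2]
  expect_equal(pen, 1 * 9.81 / 1e4, tolerance = 1e-4)
})
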