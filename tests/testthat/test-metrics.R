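test_that("duty factor is the in-contact fraction of the cycle", {
  time <- seq(0, 4, by = 0.01)
  # 1 s cycles, contact during the first 40% of each
  phase <- time %% 1
  contact <- cbind(left = phase < 0.4, right = (phase + 0.5) %% 1 < 0.4)
  df <- dutyFactor(contact, time, cycleBounds = c(0, 1, 2, 3))
  expect_equal(unname(df["left"]), 0.4, tolerance = 0.02)
  expect_equal(unname(df["right"]), 0.4, tolerance = 0.02)
  expect_equal(unname(dutyFactor(rep(TRUE, length(time)), time, c(0, 2))),
               1.0)
  expect_error(dutyFactor(contact, time, cycleBounds = 1), "complete cycle")
})

test_that("Froude number is v^2 / (g h)", {
  h <- 2.5
  expect_equal(froudeNumber(sqrt(9.81 * h), h), 1.0)
  expect_equal(froudeNumber(0, h), 0)
  expect_equal(froudeNumber(2, 1), 4 * froudeNumber(1, 1))
  expect_error(froudeNumber(1, 0), "positive")
})

test_that("stride metrics follow the kinematic identity v = stride / cycle", {
  v <- 1.7; Tc <- 0.8
  time <- seq(0, 4, by = 0.005)
  phase <- time %% Tc
  traj <- makeFakeTrajectory(time, comx = v * time, comy = rep(1, length(time)),
                             contactLeft = phase < 0.5 * Tc,
                             contactRight = (phase + Tc / 2) %% Tc < 0.5 * Tc)
  sm <- strideMetrics(traj)
  expect_equal(sm$cycleDuration, Tc, tolerance = 1e-9)
  expect_equal(sm$strideLength, v * Tc, tolerance = 1e-9)

  standing <- makeFakeTrajectory(time, comx = rep(0, length(time)),
                                 comy = rep(1, length(time)),
                                 contactLeft = rep(TRUE, length(time)),
                                 contactRight = rep(TRUE, length(time)))
  expect_error(strideMetrics(standing), "touchdowns")
})

test_that("energy phase difference hits the sinusoid anchors", {
  dt <- 0.01; Tc <- 1
  t <- seq(0, 6, by = dt)
  ke <- sin(2 * pi * t / Tc)
  expect_equal(energyPhaseDifference(ke, -ke, dt, Tc), 50)
  expect_equal(energyPhaseDifference(ke, ke, dt, Tc), 0)
  quarter <- sin(2 * pi * (t - 0.25) / Tc)
  expect_equal(energyPhaseDifference(ke, quarter, dt, Tc), 25)
  # symmetric in its arguments and amplitude-invariant
  expect_equal(energyPhaseDifference(quarter, ke, dt, Tc), 25)
  expect_equal(energyPhaseDifference(3 * ke, 0.1 * quarter, dt, Tc), 25)
  expect_error(energyPhaseDifference(ke, rep(1, length(t)), dt, Tc),
               "constant")
})

test_that("gait classification follows the aerial-phase and phase rules", {
  expect_equal(classifyGait(c(0.4, 0.4), TRUE, 10), "aerial run")
  expect_equal(classifyGait(c(0.6, 0.6), FALSE, 40), "walk")
  expect_equal(classifyGait(c(0.6, 0.6), FALSE, 5), "grounded run")
  # the threshold is configurable
  expect_equal(classifyGait(c(0.6, 0.6), FALSE, 20, walkThreshold = 15),
               "walk")
})

test_that("gait summaries assemble the full analytics from a trajectory", {
  v <- 1.2; Tc <- 1
  time <- seq(0, 6, by = 0.005)
  phase <- time %% Tc
  # walking-like: duty 0.6, no aerial phase, PE in antiphase with KE
  comy <- 1 + 0.03 * cos(2 * pi * time / (Tc / 2))
  comx <- v * time + 0.02 * sin(2 * pi * time / (Tc / 2) + pi)
  traj <- makeFakeTrajectory(time, comx, comy,
                             contactLeft = phase < 0.6 * Tc,
                             contactRight = (phase + Tc / 2) %% Tc < 0.6 * Tc)
  traj$comVel[, 1] <- v + 0.02 * 4 * pi * cos(2 * pi * time / (Tc / 2) + pi)
  gs <- gaitSummary(traj, hipHeight = 1)
  expect_equal(unname(gs$dutyFactor["left"]), 0.6, tolerance = 0.01)
  expect_false(gs$aerialPhase)
  expect_equal(gs$froude, froudeNumber(gs$meanVelocity, 1))
  expect_equal(gs$cycleDuration, Tc, tolerance = 1e-6)
  # KE and PE oscillate at half the stride period in antiphase: the lag is
  # a quarter stride, i.e. a 25% phase difference - the walk threshold
  expect_equal(gs$phaseDifference, 25, tolerance = 0.05)
  expect_equal(gs$gaitClass, "walk")

  # duty 0.4 with both feet off the ground part of the cycle: aerial run
  traj2 <- makeFakeTrajectory(time, comx, comy,
                              contactLeft = phase < 0.4 * Tc,
                              contactRight = (phase + Tc / 2) %% Tc < 0.4 * Tc)
  traj2$comVel[, 1] <- traj$comVel[, 1]
  gs2 <- gaitSummary(traj2, hipHeight = 1)
  expect_true(gs2$aerialPhase)
  expect_equal(gs2$gaitClass, "aerial run")
})

test_that("duty factor from forces agrees with duty factor from flags", {
  time <- seq(0, 3, by = 0.01)
  phase <- time %% 1
  cl <- phase < 0.45; cr <- (phase + 0.5) %% 1 < 0.45
  traj <- makeFakeTrajectory(time, time, rep(1, length(time)), cl, cr)
  ctForce <- limbContact(traj)                     # force-threshold route
  flags <- cbind(left = traj$contactFlag[, 1] > 0,
                 right = traj$contactFlag[, 2] > 0)
  cb <- c(0, 1, 2)
  expect_equal(dutyFactor(ctForce, time, cb), dutyFactor(flags, time, cb))
})
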