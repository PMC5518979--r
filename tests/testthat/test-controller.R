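test_that("cyclic controllers are periodic and symmetric by construction", {
  lv <- matrix(seq(0, 1, length.out = 8), 1, 8,
               dimnames = list("hip_ext_l", NULL))
  ctrl <- symmetricController(0.8, lv)
  expect_setequal(rownames(ctrl$levels), c("hip_ext_l", "hip_ext_r"))

  # periodicity
  expect_equal(activationsAt(ctrl, 0), activationsAt(ctrl, 0.8))
  expect_equal(activationsAt(ctrl, 0.13), activationsAt(ctrl, 0.93))

  # right limb lags the left by half a cycle
  for (t in c(0, 0.1, 0.33, 0.77)) {
    a <- activationsAt(ctrl, t)
    b <- activationsAt(ctrl, t + 0.4)
    expect_equal(unname(a[["hip_ext_r"]]), unname(b[["hip_ext_l"]]))
  }

  # constant levels give a constant signal
  cc <- cyclicController(0.5, matrix(0.5, 2, 8,
                                     dimnames = list(c("a", "b"), NULL)))
  for (t in c(0, 0.2, 0.499, 1.7))
    expect_equal(unname(activationsAt(cc, t)), c(0.5, 0.5))

  expect_error(cyclicController(0, lv), "positive")
  expect_error(cyclicController(1, lv * 3), "0, 1")
  expect_error(symmetricController(1, lv[, 1:7, drop = FALSE]), "even")
})

test_that("fitness is COM distance with early termination as its own penalty", {
  m <- attachStressMonitors(makeToyBiped())
  cfg <- simConfig(timestep = 5e-4, duration = 1.5)

  # standing still scores ~zero
  zero <- cyclicController(0.5, matrix(0, length(m$muscles), 1,
                                       dimnames = list(names(m$muscles),
                                                       NULL)))
  f0 <- evaluateFitness(m, zero, cfg, stressLimit = Inf)
  expect_lt(abs(f0$distance), 0.05)

  # the monitor is passive: an infinite limit reproduces the same motion
  # as a finite-but-never-reached one, and a binding limit truncates it
  set.seed(4)
  lv <- matrix(stats::runif(length(m$muscles) * 8), length(m$muscles), 8,
               dimnames = list(names(m$muscles), NULL))
  ctrl <- cyclicController(0.5, lv)
  fInf <- evaluateFitness(m, ctrl, cfg, stressLimit = Inf)
  fHigh <- evaluateFitness(m, ctrl, cfg, stressLimit = 1e12)
  expect_identical(fInf$distance, fHigh$distance)
  expect_identical(fInf$trajectory$com, fHigh$trajectory$com)

  lim <- max(fInf$peakStress) * 0.5
  fCut <- evaluateFitness(m, ctrl, cfg, stressLimit = lim)
  expect_equal(fCut$terminationCause, "stress_fail")
  expect_lt(fCut$elapsed, fInf$elapsed)
  # distance equals the COM displacement at the fail time
  trI <- fInf$trajectory
  comAtFail <- stats::approx(trI$time, trI$com[, 1],
                             xout = fCut$elapsed)$y
  expect_lt(abs(fCut$distance - (comAtFail - trI$com[1, 1])), 1e-4)
  # velocity = distance / elapsed
  expect_equal(fCut$meanVelocity, fCut$distance / fCut$elapsed)
})

test_that("the GA core recovers a known optimum and is seed-reproducible", {
  target <- c(0.3, 0.7)
  obj <- function(g) -sum((g - target)^2)
  cfg <- optimConfig(populationSize = 24, generations = 30, seed = 7,
                     nPhases = 2)
  r1 <- gaOptimize(obj, 2, cfg)
  expect_lt(sqrt(sum((r1$bestGenome - target)^2)), 0.05)
  r2 <- gaOptimize(obj, 2, cfg)
  expect_identical(r1$bestGenome, r2$bestGenome)
  expect_identical(r1$log, r2$log)
  # the log tracks the running best monotonically
  expect_true(all(diff(r1$log$best) >= 0))
})

test_that("morphing seeds keep the parent and stay in bounds", {
  g <- stats::runif(17)
  pop0 <- morphSeed(g, 10, scale = 0)
  expect_true(all(apply(pop0, 1, function(r) all(r == g))))
  pop <- morphSeed(g, 50, scale = 0.4, seed = 3)
  expect_equal(pop[1, ], g)
  expect_true(all(pop >= 0 & pop <= 1))
  expect_identical(pop, morphSeed(g, 50, scale = 0.4, seed = 3))
})

test_that("warm-started optimisation never loses the seed controller", {
  m <- attachStressMonitors(makeToyBiped())
  oc <- optimConfig(populationSize = 6, generations = 2, seed = 5,
                    nPhases = 8, cycleRange = c(0.3, 1.0))
  sc <- simConfig(timestep = 1e-3, duration = 1.5)
  set.seed(21)
  warmGenome <- stats::runif(bipedsim:::genomeLength(m, oc))
  warmCtrl <- decodeGenome(warmGenome, m, oc)
  warmFit <- evaluateFitness(m, warmCtrl, sc, Inf)$distance
  res <- optimizeController(m, oc, sc, stressLimit = Inf,
                            warmStart = warmGenome)
  expect_gte(res$fitness$distance, warmFit - 1e-12)
  # a returned best controller re-evaluates to its reported fitness
  again <- evaluateFitness(m, res$controller, sc, Inf)
  expect_equal(again$distance, res$fitness$distance)
})

test_that("genomes decode to valid controllers and round-trip", {
  m <- makeToyBiped()
  oc <- optimConfig(nPhases = 8, cycleRange = c(0.3, 1.2))
  ng <- bipedsim:::genomeLength(m, oc)
  expect_equal(ng, 6 * 8 + 1)             # left-side genes + cycle gene
  set.seed(2)
  g <- stats::runif(ng)
  ctrl <- decodeGenome(g, m, oc)
  expect_s3_class(ctrl, "cyclicController")
  expect_setequal(rownames(ctrl$levels), names(m$muscles))
  expect_true(ctrl$cycleDuration >= 0.3 && ctrl$cycleDuration <= 1.2)
  g2 <- bipedsim:::encodeController(ctrl, m, oc)
  expect_equal(g2, g, tolerance = 1e-12)
})
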