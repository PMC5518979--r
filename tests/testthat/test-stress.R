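hollowCircleSection <- function(R = 0.05, fraction = 0.38, n = 256) {
  hollowSectionFromOutline(
    crossSectionSpec(circleOutline(R, n), corticalFraction = fraction))
}

test_that("compressive stress is F/A", {
  sec <- sectionProperties(A = 0.005, Ix = 1e-5, Iy = 1e-5, Ixy = 0)
  expect_equal(compressiveStress(loadState(F = 10000), sec), 2e6)
  expect_equal(compressiveStress(loadState(F = 0), sec), 0)
  sec2 <- sectionProperties(A = 0.01, Ix = 1e-5, Iy = 1e-5, Ixy = 0)
  expect_equal(compressiveStress(loadState(F = 10000), sec2), 1e6)
})

test_that("bending stress follows the unsymmetric-beam formula", {
  sec <- sectionProperties(A = 1, Ix = 1e-5, Iy = 1e-5, Ixy = 0)
  expect_equal(bendingStress(loadState(Mx = 1000), sec, 0, 0.05), 5e6)
  expect_equal(bendingStress(loadState(Mx = 123, My = -42), sec, 0, 0), 0)
  # full asymmetric formula against direct evaluation
  Ix <- 3e-6; Iy <- 5e-6; Ixy <- 1e-6
  secA <- sectionProperties(A = 1, Ix = Ix, Iy = Iy, Ixy = Ixy)
  Mx <- 200; My <- -80; x <- 0.01; y <- -0.02
  D <- Ix * Iy - Ixy^2
  expect_equal(bendingStress(loadState(Mx = Mx, My = My), secA, x, y),
               (Mx * Iy + My * Ixy) / D * y - (My * Ix + Mx * Ixy) / D * x)
  bad <- list(A = 1, Ix = 1e-6, Iy = 1e-6, Ixy = 2e-6)
  expect_error(bendingStress(loadState(Mx = 1), structure(bad,
               class = "sectionProperties"), 0, 0.01), "singular")
})

test_that("pure bending integrates to zero axial force over the section", {
  sec <- hollowSectionFromOutline(
    crossSectionSpec(asymmetricSection(), corticalFraction = 1))
  # fan quadrature: the stress field is linear, so each triangle
  # contributes its area times the stress at its centroid
  b <- sec$outerBoundary
  n <- nrow(b)
  tot <- 0; totA <- 0
  load <- loadState(Mx = 500, My = -200)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    A <- 0.5 * (b[i, 1] * b[j, 2] - b[j, 1] * b[i, 2])
    cx <- (b[i, 1] + b[j, 1]) / 3
    cy <- (b[i, 2] + b[j, 2]) / 3
    tot <- tot + A * bendingStress(load, sec, cx, cy)
    totA <- totA + A
  }
  scale <- totA * abs(bendingStress(load, sec, 0, max(abs(b[, 2]))))
  expect_lt(abs(tot) / scale, 1e-9)
})

test_that("peak boundary stress matches hollow-circle closed forms", {
  R <- 0.05; fr <- 0.38
  sec <- hollowCircleSection(R, fr)
  Ri <- R * (1 - fr)
  Iclosed <- pi / 4 * (R^4 - Ri^4)
  Aclosed <- pi * (R^2 - Ri^2)
  M <- 800
  ps <- peakBoundaryStress(loadState(Mx = M), sec)
  expect_equal(ps$max, M * R / Iclosed, tolerance = 1e-3)
  expect_equal(ps$min, -M * R / Iclosed, tolerance = 1e-3)

  # pure axial load: uniform field
  F <- -5000
  pa <- peakBoundaryStress(loadState(F = F), sec)
  expect_equal(pa$max, F / sec$A)
  expect_equal(pa$min, F / sec$A)

  # superposition: max + min = 2 F / A under combined load
  pc <- peakBoundaryStress(loadState(F = F, Mx = M), sec)
  expect_equal(pc$max + pc$min, 2 * F / sec$A, tolerance = 1e-9)
})

test_that("peak boundary stress is invariant under joint rotation of section and moment", {
  poly <- asymmetricSection()
  load <- loadState(F = -2000, Mx = 400, My = 150)
  sec0 <- hollowSectionFromOutline(crossSectionSpec(poly, 0.5))
  p0 <- peakBoundaryStress(load, sec0)
  for (alpha in c(0.3, 1.2, 2.5)) {
    Rm <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
    secR <- hollowSectionFromOutline(crossSectionSpec(poly %*% t(Rm), 0.5))
    Mr <- Rm %*% c(load$Mx, load$My)
    pR <- peakBoundaryStress(loadState(F = load$F, Mx = Mr[1], My = Mr[2]),
                             secR)
    expect_equal(pR$max, p0$max, tolerance = 1e-6)
    expect_equal(pR$min, p0$min, tolerance = 1e-6)
  }
})

test_that("max boundary stress is monotone in the bending magnitude", {
  sec <- hollowCircleSection()
  peaks <- vapply(seq(0, 2000, by = 250), function(M)
    peakBoundaryStress(loadState(F = -1000, Mx = M), sec)$max, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("causal Butterworth filter has unit DC gain and -3 dB at the cutoff", {
  fs <- 1000
  x <- rep(3.3, 200)
  expect_equal(butterworthLowpass(x, fs), x)
  expect_equal(butterworthLowpass(rep(0, 100), fs), rep(0, 100))

  t <- seq(0, 4, by = 1 / fs)
  s <- sin(2 * pi * 5 * t)
  f <- butterworthLowpass(s, fs, cutoff = 5, order = 2)
  amp <- max(f[t > 2])                      # steady state
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.01)

  expect_error(butterworthLowpass(s, 8, cutoff = 5), "Nyquist")
})

test_that("the filter is linear and the zero-phase mode preserves DC", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  s1 <- sin(2 * pi * 2 * t) + 0.3
  s2 <- cos(2 * pi * 7 * t)
  a <- 1.7; b <- -0.4
  lhs <- butterworthLowpass(a * s1 + b * s2, fs)
  rhs <- a * butterworthLowpass(s1, fs) + b * butterworthLowpass(s2, fs)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_equal(butterworthLowpass(rep(2, 100), fs, mode = "zero-phase"),
               rep(2, 100))
})

test_that("the stress fail monitor reports the first exceedance", {
  tgrid <- seq(0, 2, by = 0.01)
  tr1 <- matrix(50e6, length(tgrid), 2,
                dimnames = list(NULL, c("femur", "tibia")))
  expect_true(stressFailMonitor(tr1, limit = 100e6)$passed)

  tr2 <- tr1
  tr2[tgrid >= 0.8, 2] <- 120e6
  res <- stressFailMonitor(tr2, limit = 100e6, time = tgrid)
  expect_false(res$passed)
  expect_equal(res$time, 0.8)
  expect_equal(res$bone, "tibia")

  # a 100 MPa limit is safety factor 2 on a 200 MPa yield strength
  yield <- 200e6
  tr3 <- matrix(c(99e6, 101e6), 2, 1)
  expect_true(stressFailMonitor(tr3, limit = yield / 2)$passed == FALSE)
  expect_true(stressFailMonitor(tr3[1, , drop = FALSE],
                                limit = yield / 2)$passed)
})

test_that("stressTrace objects validate and feed the monitor", {
  tgrid <- seq(0, 1, by = 0.01)
  raw <- matrix(10e6, length(tgrid), 1)
  st <- stressTrace(tgrid, raw, raw * 0.9, limit = 50e6)
  expect_true(stressFailMonitor(st)$passed)
  expect_error(stressTrace(tgrid, raw, raw[-1, , drop = FALSE], 50e6),
               "equal dimensions")
  expect_error(stressTrace(tgrid, raw, raw, 0), "positive")
})
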