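# Band integration, expectation frequency and sequential kinetics.

test_that("band integration handles edges, zeros and Gaussians", {
  grid <- seq(1500, 1650, by = 0.5)
  zero <- Spectrum(grid, rep(0, length(grid)))
  expect_equal(integrateBand(zero, c(1550, 1600)), 0)

  flat <- Spectrum(grid, rep(1, length(grid)))
  expect_equal(integrateBand(flat, c(1550, 1600)), 50)
  # window edges off the grid points still integrate exactly
  expect_equal(integrateBand(flat, c(1550.3, 1600.7)), 50.4)

  g <- convolveSpectrum(data.frame(position = 1575, intensity = 2),
                        grid, fwhm = 5)
  expect_lt(abs(integrateBand(g, c(1550, 1600)) - 2) / 2, 1e-3)

  expect_error(integrateBand(flat, c(1700, 1800)), "overlap")
})

test_that("expectation frequency is an intensity-weighted mean", {
  grid <- seq(1500, 1650, by = 0.5)
  g <- convolveSpectrum(data.frame(position = 1580, intensity = 1),
                        grid, fwhm = 6)
  expect_equal(expectationFrequency(g, c(1550, 1610)), 1580,
               tolerance = 1e-6)

  sticks <- data.frame(position = c(1560, 1580), intensity = c(1, 3))
  expect_equal(expectationFrequency(sticks, c(1500, 1600)), 1575)

  # invariant under uniform intensity scaling
  g2 <- Spectrum(spectrumGrid(g), 7.3 * spectrumValues(g))
  expect_equal(expectationFrequency(g2, c(1550, 1610)),
               expectationFrequency(g, c(1550, 1610)))

  # invariant under grid refinement
  gridFine <- seq(1500, 1650, by = 0.1)
  gF <- convolveSpectrum(data.frame(position = 1580, intensity = 1),
                         gridFine, fwhm = 6)
  expect_equal(expectationFrequency(gF, c(1550, 1610)),
               expectationFrequency(g, c(1550, 1610)),
               tolerance = 1e-4)

  # bleach-dominated windows are refused
  neg <- Spectrum(grid, rep(-1, length(grid)))
  expect_error(expectationFrequency(neg, c(1550, 1600)), "positive")
})

test_that("intensity breakdown partitions by band kind", {
  onlyF <- data.frame(position = c(1560, 1590),
                      intensity = c(1, 2),
                      kind = c("fundamental", "fundamental"))
  expect_equal(intensityBreakdown(onlyF, c(1500, 1600)),
               c(fundamental = 1, combination = 0, overtone = 0))

  mixed <- data.frame(position = c(1560, 1570, 1580),
                      intensity = c(2, 2, 2),
                      kind = c("fundamental", "combination", "overtone"))
  expect_equal(unname(intensityBreakdown(mixed, c(1500, 1600))),
               rep(1 / 3, 3))

  # empty window gives zeros
  expect_equal(sum(intensityBreakdown(mixed, c(1700, 1800))), 0)

  # fixture cross-check against a hand sum
  sys <- vibrationalSystem(
    c(1560, 1580), rbind(c(-5, -3), c(-3, -6)),
    fundIntensities = c(1, 2), overtoneIntensities = c(0.1, 0.1),
    combIntensities = rbind(c(0, 0.5), c(0.5, 0)))
  st <- stickSpectrum(sys, c(0, 0), window = c(1000, 3500))
  bd <- intensityBreakdown(st, c(1000, 3500))
  byKind <- tapply(st$intensity, st$kind, sum)
  expect_equal(bd[["fundamental"]],
               unname(byKind["fundamental"] / sum(st$intensity)))
  expect_equal(sum(bd), 1)
})

test_that("sequential populations follow the two-step closed form", {
  p0 <- sequentialPopulations(0, 0.5, 5)
  expect_equal(p0$S0star, 0)
  expect_equal(p0$S1, 1)

  p1 <- sequentialPopulations(1, 0.5, 5)
  expect_equal(p1$S0star, (2 / (0.2 - 2)) * (exp(-2) - exp(-0.2)),
               tolerance = 1e-12)

  # conservation on a dense grid
  tt <- seq(0, 40, by = 0.05)
  p <- sequentialPopulations(tt, 0.7, 6)
  expect_true(all(abs(p$S1 + p$S0star + p$S0 - 1) < 1e-12))

  # tau2 -> tau1 limit approaches k t e^{-kt}
  k <- 2
  pLim <- sequentialPopulations(tt, 1 / k, 1 / k * (1 + 1e-4))
  expect_lt(max(abs(pLim$S0star - k * tt * exp(-k * tt))), 1e-4)
  pDeg <- sequentialPopulations(tt, 1 / k, 1 / k)
  expect_lt(max(abs(pDeg$S0star - k * tt * exp(-k * tt))), 1e-6)

  # components vanish before time zero
  pNeg <- sequentialPopulations(c(-5, -0.1), 0.5, 5)
  expect_true(all(pNeg == 0))

  expect_error(sequentialPopulations(1, -1, 5), "positive")
})

test_that("IRF convolution smooths the rise without changing the tail", {
  tt <- seq(-2, 30, by = 0.02)
  a <- sequentialModel(tt, 0.5, 5, c(0, 1, 0))
  b <- sequentialModel(tt, 0.5, 5, c(0, 1, 0), irf = 0.2)
  expect_gt(b[which.min(abs(tt + 0.1))], 0)  # smooth rise before t = 0
  # the long tail only carries the tiny e^{(sigma k)^2/2} factor
  late <- tt > 10
  expect_lt(max(abs(a[late] - b[late])), 1e-3)
})

test_that("sequential fits recover known parameters", {
  tt <- seq(0.1, 30, length.out = 60)
  y <- sequentialModel(tt, 0.5, 5, c(0.2, 1, 0.3), baseline = 0.05)
  # the constant offset aliases into the population amplitudes at t >= 0
  fit <- fitSequential(data.frame(time = tt, value = y),
                       tau1 = 0.3, tau2 = 8)
  expect_equal(fit$tau1, 0.5, tolerance = 5e-4)
  expect_equal(fit$tau2, 5, tolerance = 5e-4)
  expect_true(fit$identifiable)

  # constant trace: unidentifiable lifetimes are flagged
  flatFit <- fitSequential(data.frame(time = tt,
                                      value = rep(0.4, length(tt))),
                           tau1 = 0.5, tau2 = 5)
  expect_false(flatFit$identifiable)
  expect_null(flatFit$se)
})
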