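# Kinetic Monte Carlo cooling.

test_that("step probabilities carry the right units and factors", {
  sys <- vibrationalSystem(1000)
  p <- stepProbabilities(sys, 1, kmcParams(q = 0.1, dt = 5))
  expect_equal(p$pDown, 0.1 * 1 * 1000 * 2.99792458e-5 * 5,
               tolerance = 1e-12)
  p0 <- stepProbabilities(sys, 0, kmcParams(q = 0.1, dt = 5, TBath = 300))
  expect_identical(p0$pDown, 0)
  expect_equal(p0$pUp,
               0.1 * 1 * 1000 * 2.99792458e-5 * 5 *
                 exp(-1000 / kBT(300)),
               tolerance = 1e-12)
  # ~1.24e-4, the bath-uptake probability of a cold mid-IR mode
  expect_equal(p0$pUp, 1.24e-4, tolerance = 0.01)

  # per-mode overrides and the clipping warning
  p2 <- stepProbabilities(vibrationalSystem(c(500, 1000)), c(1, 1),
                          kmcParams(qi = c(0.2, 0.1), dt = 5))
  expect_equal(p2$pDown[1] / p2$pDown[2], (0.2 * 500) / (0.1 * 1000))
  expect_warning(
    stepProbabilities(sys, 800, kmcParams(q = 1, dt = 100)), "clipped")
})

test_that("a step without proposal draws leaves the configuration alone", {
  sys <- vibrationalSystem(c(800, 1200))
  params <- kmcParams(q = 1e-12, dt = 1e-3, acceptanceMode = "none")
  set.seed(401)
  expect_equal(kmcStep(sys, c(3, 1), params), c(3, 1))
})

test_that("acceptance conventions behave as specified", {
  # as_printed accepts every uphill move and damps downhill moves by
  # the Boltzmann factor of the transition energy
  nu <- 500
  sys <- vibrationalSystem(nu)
  params <- kmcParams(q = 2, dt = 5, acceptanceMode = "as_printed")
  set.seed(402)
  nDownAcc <- 0L
  nDownProp <- 0L
  n <- 5L
  for (k in 1:4000) {
    n2 <- kmcStep(sys, n, params)
    if (n2 < n) nDownAcc <- nDownAcc + 1L
    nDownProp <- nDownProp + 1L  # p_down = 2*5*500*c*dt = 0.15 per step
    n <- 5L
  }
  pDown <- stepProbabilities(sys, 5, params)$pDown
  target <- pDown * exp(-nu / kBT(300))
  frac <- nDownAcc / nDownProp
  se <- sqrt(target * (1 - target) / nDownProp)
  expect_lt(abs(frac - target), 4 * se + 1e-4)
})

test_that("harmonic equilibrium matches Bose-Einstein occupation", {
  # proposal rates alone satisfy detailed balance in the harmonic limit
  sys <- vibrationalSystem(500)
  params <- kmcParams(q = 0.1, dt = 5, tMax = 2e6, TBath = 300,
                      acceptanceMode = "none")
  set.seed(403)
  tr <- runTrajectory(sys, 0, params, recordSpectra = FALSE)
  occ <- tr$totalQuanta[-(1:20000)]  # burn-in
  target <- refBoseEinstein(500, 300)
  se <- blockSE(occ, 80)
  expect_lt(abs(mean(occ) - target), 3 * se)
})

test_that("hot ensembles cool toward the thermal mean energy", {
  sys <- vibrationalSystem(c(400, 700, 1000),
                           diag(c(-5, -8, -10)))
  params <- kmcParams(q = 0.3, dt = 5, tMax = 6000, TBath = 300,
                      acceptanceMode = "none", nTrajectories = 24,
                      spectralWindow = c(300, 1100))
  hot <- matrix(c(8, 4, 3), nrow = 1)  # ~ 9400 cm-1
  sm <- ensembleSpectra(sys, hot, params, thermalT = 0, seed = 404)
  me <- smMetadata(sm)$meanEnergy
  eTherm <- sum(scaledFrequencies(sys) *
                  refBoseEinstein(scaledFrequencies(sys), 300))
  expect_gt(me[1], 8000)
  tail <- mean(me[me > 0 & seq_along(me) > 0.8 * length(me)])
  expect_lt(tail, 0.1 * me[1])
  expect_lt(abs(tail - eTherm), 150)  # plateau near the 300 K mean
  # ensemble-mean energy is (noise-bounded) non-increasing
  sm3 <- stats::filter(me, rep(1 / 51, 51), sides = 2)
  sm3 <- sm3[!is.na(sm3)]
  expect_true(all(diff(sm3) < 20))
})

test_that("a zero-length trajectory records the initial spectrum once", {
  sys <- vibrationalSystem(c(1400, 1600), fundIntensities = c(1, 2))
  params <- kmcParams(tMax = 0, spectralWindow = c(1350, 1850))
  tr <- runTrajectory(sys, c(0, 0), params)
  expect_equal(nrow(tr$rows), 1)
  st <- stickSpectrum(sys, c(0, 0), window = c(1350, 1850))
  expect_equal(sum(tr$rows[1, ]), sum(st$intensity))
  expect_equal(tr$energies, 0)
})

test_that("already-thermal ensembles show no energy trend", {
  sys <- vibrationalSystem(c(300, 600))
  params <- kmcParams(q = 0.5, dt = 5, tMax = 4000, TBath = 300,
                      acceptanceMode = "none", nTrajectories = 40,
                      spectralWindow = c(250, 700))
  sm <- ensembleSpectra(sys, matrix(0L, 1, 2), params, thermalT = 300,
                        seed = 405)
  me <- smMetadata(sm)$meanEnergy
  fit <- lm(me ~ rowAxis(sm))
  slope <- coef(summary(fit))[2, ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"] + 0.02)
})

test_that("ensemble averaging is linear in the initial configurations", {
  # vanishing rates freeze the configurations, so the ensemble averages
  # are exact sums of the initial-configuration spectra
  sys <- vibrationalSystem(c(500, 900), diag(c(-4, -6)))
  params <- kmcParams(q = 1e-9, dt = 5, tMax = 250,
                      acceptanceMode = "none", nTrajectories = 3,
                      spectralWindow = c(400, 1000))
  a <- matrix(c(2L, 0L), 1)
  b <- matrix(c(0L, 2L), 1)
  smA <- ensembleSpectra(sys, a, params, thermalT = 0, seed = 77)
  smB <- ensembleSpectra(sys, b, params, thermalT = 0, seed = 77)
  smAB <- ensembleSpectra(sys, rbind(a, b), params, thermalT = 0,
                          seed = 77)
  expect_equal(spectralValues(smAB),
               spectralValues(smA) + spectralValues(smB))
  expect_equal(sampleCounts(smAB)[1],
               sampleCounts(smA)[1] + sampleCounts(smB)[1])
})
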