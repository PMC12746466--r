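# Dunham energetics: total energies, transition energies, intensities.

test_that("total energy matches direct evaluation of the expansion", {
  expect_equal(totalEnergy(vibrationalSystem(1000), 3), 3000)
  sys1 <- vibrationalSystem(1000, matrix(-10, 1, 1))
  expect_equal(totalEnergy(sys1, 1), 980)
  sys2 <- vibrationalSystem(c(1000, 1500),
                            rbind(c(-10, -5), c(-5, -12)))
  expect_equal(totalEnergy(sys2, c(1, 1)), 2446)
  expect_identical(totalEnergy(sys2, c(0, 0)), 0)

  set.seed(101)
  for (k in 1:20) {
    sys <- randomSystem(sample(1:4, 1), offScale = 2)
    n <- sample(0:4, nModes(sys), replace = TRUE)
    expect_equal(totalEnergy(sys, n), refEnergy(sys, n))
  }
})

test_that("energy is additive over modes without cross couplings", {
  set.seed(102)
  sys <- randomSystem(4, offScale = 0)
  n <- c(2, 0, 3, 1)
  nu <- modeFrequencies(sys)
  xd <- diag(xMatrix(sys))
  expect_equal(totalEnergy(sys, n), sum(nu * n + xd * (n^2 + n)))
})

test_that("frequency scaling multiplies frequencies but not X", {
  sys <- vibrationalSystem(1000, matrix(-10, 1, 1), freqScale = 0.992)
  expect_equal(totalEnergy(sys, 1), 992 - 20)
  expect_equal(scaledFrequencies(sys), 992)
})

test_that("transition energies by differencing match the closed forms", {
  # harmonic: fundamental is nu at any occupation
  h <- vibrationalSystem(c(700, 1100))
  for (n1 in 0:3)
    expect_equal(transitionEnergy(h, c(n1, 2), "fundamental", 1), 700)

  sys1 <- vibrationalSystem(1000, matrix(-10, 1, 1))
  expect_equal(transitionEnergy(sys1, 0, "fundamental", 1), 980)
  expect_equal(transitionEnergy(sys1, 0, "overtone", 1), 1940)
  sysC <- vibrationalSystem(c(1000, 1500), rbind(c(0, -5), c(-5, 0)))
  expect_equal(transitionEnergy(sysC, c(0, 0), "combination", c(1, 2)),
               2490)

  # closed form nu_i + X_ii(2n_i + 2) + sum_{j != i} X_ij (n_j + 1/2)
  set.seed(103)
  for (k in 1:15) {
    sys <- randomSystem(3, offScale = 3)
    n <- sample(0:3, 3, replace = TRUE)
    i <- sample(1:3, 1)
    X <- xMatrix(sys)
    closed <- modeFrequencies(sys)[i] + X[i, i] * (2 * n[i] + 2) +
      sum(X[i, -i] * (n[-i] + 0.5))
    expect_equal(transitionEnergy(sys, n, "fundamental", i), closed)
  }
})

test_that("invalid configurations and indices are rejected", {
  sys <- vibrationalSystem(c(1000, 1500))
  expect_error(totalEnergy(sys, c(1, 2, 3)), "does not match")
  expect_error(totalEnergy(sys, c(-1, 0)), "non-negative")
  expect_error(totalEnergy(sys, c(0.5, 0)), "non-negative integers")
  expect_error(transitionEnergy(sys, c(0, 0), "fundamental", 3),
               "out of range")
  expect_error(transitionEnergy(sys, c(0, 0), "combination", c(1, 1)),
               "distinct")
})

test_that("line intensities follow the occupancy and energy-ratio rule", {
  # harmonic identity case and (n+1) scaling
  h <- vibrationalSystem(1000, fundIntensities = 2.5)
  expect_equal(lineIntensity(h, 0, "fundamental", 1), 2.5)
  for (n in 0:4)
    expect_equal(lineIntensity(h, n, "fundamental", 1), 2.5 * (n + 1))

  sys <- vibrationalSystem(1000, matrix(-10, 1, 1), fundIntensities = 1)
  expect_equal(lineIntensity(sys, 1, "fundamental", 1),
               2 * 960 / 980)

  # negative transition energy: nu = 100, X = -30, n = 1 has
  # dE(1 -> 2) = 100 - 30 * 4 < 0
  steep <- vibrationalSystem(100, matrix(-30, 1, 1), fundIntensities = 1)
  expect_lt(transitionEnergy(steep, 1, "fundamental", 1), 0)
  expect_identical(lineIntensity(steep, 1, "fundamental", 1), 0)
})

test_that("overtone and combination intensities use their own scalings", {
  sys <- vibrationalSystem(
    c(800, 1200), rbind(c(-8, -2), c(-2, -12)),
    fundIntensities = c(1, 1),
    overtoneIntensities = c(0.2, 0.1),
    combIntensities = rbind(c(0, 0.3), c(0.3, 0)))
  n <- c(1, 2)
  dE <- transitionEnergy(sys, n, "overtone", 1)
  dE0 <- transitionEnergy(sys, c(0, 0), "overtone", 1)
  expect_equal(lineIntensity(sys, n, "overtone", 1),
               0.2 * (2 * 3 / 2) * dE / dE0)
  dEc <- transitionEnergy(sys, n, "combination", c(1, 2))
  dEc0 <- transitionEnergy(sys, c(0, 0), "combination", c(1, 2))
  expect_equal(lineIntensity(sys, n, "combination", c(1, 2)),
               0.3 * (2 * 3) * dEc / dEc0)
  # occupancy scaling can be turned off
  expect_equal(lineIntensity(sys, n, "overtone", 1,
                             occupancyScaling = FALSE),
               0.2 * dE / dE0)
})
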