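# Multicanonical flat-histogram sampling.

test_that("proposal moves have the advertised per-mode statistics", {
  set.seed(301)
  N <- 87
  r <- 1.08
  n0 <- rep(2L, N)
  nProp <- 4000
  nDown <- nUp <- 0
  dTot <- numeric(nProp)
  for (k in seq_len(nProp)) {
    p <- proposeConfig(n0, r)
    d <- p$config - n0
    nDown <- nDown + sum(d == -1)
    nUp <- nUp + sum(d == 1)
    dTot[k] <- sum(d)
  }
  trials <- nProp * N
  # per-mode down 1/N, up r/N (3 sigma binomial)
  expect_lt(abs(nDown / trials - 1 / N),
            3 * sqrt((1 / N) * (1 - 1 / N) / trials))
  expect_lt(abs(nUp / trials - r / N),
            3 * sqrt((r / N) * (1 - r / N) / trials))
  # expected quanta gain per proposal is r - 1 when no mode is at 0
  expect_lt(abs(mean(dTot) - (r - 1)), 3 * sd(dTot) / sqrt(nProp))
})

test_that("generation probabilities reduce to the r^dn Hastings factor", {
  set.seed(302)
  for (k in 1:50) {
    n <- sample(0:2, 5, replace = TRUE)
    p <- proposeConfig(n, 1.3)
    expect_equal(exp(p$logRev - p$logFwd), 1.3^p$deltaN,
                 tolerance = 1e-12)
  }
  # all modes at zero with an all-stay draw returns the same config
  set.seed(4)
  p <- proposeConfig(rep(0L, 3), 0.05)  # up prob tiny: almost surely stay
  expect_equal(p$config, rep(0L, 3))
  expect_equal(p$deltaN, 0)
})

test_that("window validation enforces energy range and bound states", {
  h <- vibrationalSystem(c(500, 700))
  win <- energyWindow(0, 1600, 16)
  expect_true(validateConfig(h, c(0, 0), win))
  expect_false(validateConfig(h, c(2, 1), win))  # 1700 above window

  steep <- vibrationalSystem(100, matrix(-30, 1, 1))
  win2 <- energyWindow(0, 160, 16)
  # n = 1 (E = 40) is in the window but its next fundamental is negative
  expect_false(validateConfig(steep, 1, win2))
  expect_error(energyWindow(0, 100, 16), "multiples")
})

test_that("acceptance follows the density ratio with the quanta bias", {
  dos <- new("DensityOfStates", binWidth = 16,
             counts = c(10, 20, 0, 5))
  expect_equal(mucaAcceptance(dos, 8, 8, 1.08, 0), 1)
  expect_equal(mucaAcceptance(dos, 8, 24, 1.08, -1),
               0.5 / 1.08, tolerance = 1e-12)
  # cap at one
  expect_equal(mucaAcceptance(dos, 24, 8, 1.08, 1), 1)
  # zero-density target bin rejects
  expect_equal(mucaAcceptance(dos, 8, 40, 1.08, 0), 0)
})

test_that("flatness criterion matches its definition", {
  expect_true(flatness(rep(7, 5), 0.01))
  expect_false(flatness(c(100, 100, 160), 0.25))  # max dev = 1/3
  expect_true(flatness(c(100, 100, 160), 0.34))
  expect_true(flatness(42, 0.1))
  expect_false(flatness(c(0, 0), 0.25))
  expect_error(flatness(numeric(0), 0.25), "non-empty")
})

test_that("a walk over a small harmonic ladder visits states uniformly", {
  sys <- vibrationalSystem(1000, fundIntensities = 1)
  win <- energyWindow(0, 3000, 1000)
  dos <- countStates(sys, 3000, binWidth = 1000)
  # single flatness check at the end so the visitation statistics rest
  # on a fixed, long sample
  params <- mucaParams(nWalks = 1, maxSteps = 2e5, checkEvery = 2e5,
                       spectralWindow = c(900, 1100), spectralBin = 10)
  set.seed(303)
  walk <- runWalk(sys, win, params, dos, trackConfigs = TRUE)
  expect_true(walk$converged)
  expect_true(flatness(walk$hist, 0.25))
  expect_identical(walk$samples, walk$hist)
  expect_equal(sum(walk$hist), walk$steps)
  # three states (n = 0, 1, 2): visitation uniform well within the
  # correlated-walk sampling error (~1%) and far tighter than the bias
  # a missing Hastings correction would introduce (~8%)
  tab <- table(walk$visited)
  expect_equal(length(tab), 3)
  expected <- walk$steps / 3
  expect_true(all(abs(tab - expected) / expected < 0.03))
})

test_that("canonical reweighting recovers the cold-limit ground spectrum", {
  sys <- vibrationalSystem(c(600, 900), fundIntensities = c(1, 2))
  win <- energyWindow(0, 2000, 100)
  dos <- countStates(sys, 2000, binWidth = 100)
  params <- mucaParams(nWalks = 2, maxSteps = 1e5, checkEvery = 1000,
                       spectralWindow = c(500, 1000), spectralBin = 1)
  set.seed(304)
  w1 <- runWalk(sys, win, params, dos)
  w2 <- runWalk(sys, win, params, dos)
  sm <- spectralMatrix(rowAxis = binCenters(dos),
                       colAxis = w1$spectralGrid,
                       values = w1$rows + w2$rows,
                       samples = w1$hist + w2$hist, rowType = "energy")
  spCold <- suppressWarnings(assembleCanonicalSpectrum(sm, dos, 5))
  ref <- numeric(length(spectrumValues(spCold)))
  st <- stickSpectrum(sys, c(0, 0), window = c(500, 1000))
  idx <- floor(st$position - 500) + 1
  ref[idx] <- st$intensity
  expect_equal(spectrumValues(spCold), ref, tolerance = 1e-6)

  # doubling all sample counts leaves the assembly invariant
  sm2 <- spectralMatrix(rowAxis = binCenters(dos),
                        colAxis = w1$spectralGrid,
                        values = 2 * (w1$rows + w2$rows),
                        samples = 2 * (w1$hist + w2$hist),
                        rowType = "energy")
  expect_equal(
    spectrumValues(suppressWarnings(
      assembleCanonicalSpectrum(sm2, dos, 5))),
    spectrumValues(spCold))
})

test_that("window partitioning does not change the canonical spectrum", {
  # coupled toy: energies carry the full X, the density stays separable
  sys <- coupledToy()
  p <- function() mucaParams(nWalks = 2, maxSteps = 1e5,
                             spectralWindow = c(100, 500),
                             checkEvery = 2000)
  res2 <- suppressWarnings(
    mucaSpectrum(sys, 300, eMax = 1200, nWindows = 2, binWidth = 16,
                 params = p(), seed = 21))
  res4 <- suppressWarnings(
    mucaSpectrum(sys, 300, eMax = 1200, nWindows = 4, binWidth = 16,
                 params = p(), seed = 22))
  a <- spectrumValues(res2$spectrum)
  b <- spectrumValues(res4$spectrum)
  expect_lt(sum(abs(a - b)) / sum(a), 0.10)
})
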