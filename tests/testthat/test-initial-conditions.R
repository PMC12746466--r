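# Initial-condition generation: geometry projection, thermal and
# statistical sampling.

# A small synthetic reference frame with two orthonormal mass-weighted
# "modes" for a 3-atom bent molecule.
makeModeFixture <- function() {
  ref <- geometry(c("O", "H", "H"),
                  rbind(c(0, 0, 0),
                        c(0.96, 0, 0),
                        c(-0.24, 0.93, 0)))
  v1 <- c(0, 0, 0, 1, 0, 0, -1, 0, 0)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(0, 1, 0, 0, -0.5, 0, 0, -0.5, 0)
  v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  normalModeSet(ref, c(1500, 3000), cbind(v1, v2))
}

# Displace the reference along mode k by amplitude a (in the
# mass-weighted frame), i.e. dx = a * v / sqrt(m).
displaceAlong <- function(modeset, k, a) {
  ref <- modeset$reference
  v <- matrix(modeset$vectors[, k], ncol = 3, byrow = TRUE)
  dx <- a * v / sqrt(ref$masses)
  geometry(ref$symbols, ref$coords + dx, ref$masses)
}

test_that("an undisplaced hop with no energy gives the ground state", {
  ms <- makeModeFixture()
  hop <- hopRecord(ms$reference, 0)
  expect_identical(projectHopOccupations(ms, hop), integer(2))
})

test_that("displacement along one mode forces a single-mode partition", {
  ms <- makeModeFixture()
  g <- displaceAlong(ms, 1, 0.15)
  hop <- hopRecord(g, 3 * 1500)
  expect_equal(projectHopOccupations(ms, hop), c(3L, 0L))
})

test_that("projection is invariant to rigid rotation and mass-consistent
           rescaling", {
  ms <- makeModeFixture()
  g <- displaceAlong(ms, 2, 0.2)
  hop <- hopRecord(g, 6000)
  n0 <- projectHopOccupations(ms, hop)
  expect_gt(n0[2], 0)

  # rotate the hop geometry rigidly: projections unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
             c(0, 0, 1))
  gRot <- geometry(g$symbols, g$coords %*% t(R), g$masses)
  expect_identical(projectHopOccupations(ms, hopRecord(gRot, 6000)), n0)

  # double all masses and shrink the displacement by sqrt(2): the
  # mass-weighted displacement (and hence the projection) is unchanged
  ref <- ms$reference
  ref2 <- geometry(ref$symbols, ref$coords, 2 * ref$masses)
  ms2 <- normalModeSet(ref2, ms$frequencies, ms$vectors)
  g2 <- geometry(ref$symbols,
                 ref$coords + (g$coords - ref$coords) / sqrt(2),
                 2 * ref$masses)
  expect_identical(projectHopOccupations(ms2, hopRecord(g2, 6000)), n0)
})

test_that("projection conserves energy to within one quantum", {
  ms <- makeModeFixture()
  set.seed(501)
  for (k in 1:20) {
    a <- runif(2, -0.3, 0.3)
    g <- displaceAlong(ms, 1, a[1])
    g <- geometry(g$symbols,
                  g$coords + (displaceAlong(ms, 2, a[2])$coords -
                                ms$reference$coords),
                  g$masses)
    dE <- runif(1, 500, 20000)
    n <- projectHopOccupations(ms, hopRecord(g, dE))
    expect_lte(abs(sum(n * ms$frequencies) - dE),
               max(ms$frequencies[n > 0], ms$frequencies[1]))
  }
})

test_that("projection errors on mismatched atoms and on zero
           displacement with energy to place", {
  ms <- makeModeFixture()
  bad <- geometry(c("O", "H", "D"), ms$reference$coords)
  expect_error(projectHopOccupations(ms, hopRecord(bad, 100)),
               "do not match")
  expect_error(projectHopOccupations(ms, hopRecord(ms$reference, 100)),
               "no direction")
})

test_that("thermal sampling reproduces Bose-Einstein occupations", {
  expect_identical(sampleThermalConfig(vibrationalSystem(c(100, 500)), 0),
                   integer(2))
  # repeated calls to a many-mode single-frequency system = iid draws
  sys <- makeHarmonicSystem(rep(208.51044, 500))
  set.seed(502)
  draws <- unlist(lapply(1:200, function(i) sampleThermalConfig(sys, 300)))
  target <- 1 / (exp(1) - 1)        # ~0.5820
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - target), 3 * se)

  # a 3000 cm-1 mode is essentially never occupied at 300 K
  hi <- makeHarmonicSystem(rep(3000, 500))
  set.seed(5021)
  expect_true(all(replicate(20, sampleThermalConfig(hi, 300)) == 0))
})

test_that("statistical sampling is uniform over the in-band states", {
  sys <- makeHarmonicSystem(c(97, 103, 151))
  lo <- 270; hi <- 330
  bf <- bruteForceStates(sys, hi + 1)
  inBand <- bf$energies >= lo & bf$energies <= hi
  nStates <- sum(inBand)
  expect_gt(nStates, 3)
  keys <- apply(bf$configs[inBand, , drop = FALSE], 1, paste,
                collapse = ",")

  set.seed(503)
  draws <- sampleStatisticalConfigs(sys, rep(300, 400), tol = 30)
  drawKeys <- apply(draws, 1, paste, collapse = ",")
  expect_true(all(drawKeys %in% keys))
  counts <- table(factor(drawKeys, levels = keys))
  chi <- suppressWarnings(chisq.test(counts))
  expect_gt(chi$p.value, 0.01)
})

test_that("the walk route stays inside wide energy bands", {
  sys <- makeHarmonicSystem(c(97, 103, 151))
  set.seed(504)
  draws <- sampleStatisticalConfigs(sys, rep(400, 40), tol = 150,
                                    method = "walk")
  E <- apply(draws, 1, function(n) totalEnergy(sys, n))
  expect_true(all(E >= 250 & E <= 550))
  expect_gt(length(unique(apply(draws, 1, paste, collapse = ","))), 3)
})

test_that("statistical sampling handles degenerate targets", {
  sys <- makeHarmonicSystem(c(400, 650))
  # target below the lowest excited level: ground configuration
  out <- sampleStatisticalConfigs(sys, 100, tol = 150)
  expect_identical(out[1, ], c(0L, 0L))
  # zero tolerance with an incommensurate target is unreachable
  expect_error(
    sampleStatisticalConfigs(sys, 333.33, tol = 0, maxTries = 50),
    "no configuration")
})
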