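# Independent oracles and shared fixtures for the test suite.
# The oracles deliberately re-derive everything from the raw expansion
# (naive loops, no shared code with the package internals).

# Naive Dunham energy: E(n) = sum_i nu_i (n_i + 1/2)
#                             + sum_{i<=j} X_ij (n_i+1/2)(n_j+1/2)
refDunhamAbsolute <- function(nu, X, n, scale = 1) {
  nu <- nu * scale
  h <- n + 0.5
  E <- sum(nu * h)
  N <- length(nu)
  for (i in seq_len(N)) for (j in i:N) E <- E + X[i, j] * h[i] * h[j]
  E
}

refEnergy <- function(sys, n) {
  nu <- modeFrequencies(sys)
  X <- xMatrix(sys)
  refDunhamAbsolute(nu, X, n, freqScale(sys)) -
    refDunhamAbsolute(nu, X, rep(0, length(nu)), freqScale(sys))
}

# Random small anharmonic system for property tests (diagonal-only X
# unless offScale > 0).
randomSystem <- function(nModes, fMin = 80, fMax = 1200,
                         xMin = -25, xMax = 0, offScale = 0) {
  freqs <- runif(nModes, fMin, fMax)
  X <- matrix(0, nModes, nModes)
  if (offScale > 0) {
    X[upper.tri(X)] <- -runif(nModes * (nModes - 1) / 2, 0, offScale)
    X <- X + t(X)
  }
  diag(X) <- runif(nModes, xMin, xMax)
  vibrationalSystem(freqs, X, fundIntensities = runif(nModes, 0.5, 2))
}

# Bin energies exactly as the package's half-open convention.
refBinCounts <- function(energies, binWidth, nBins) {
  counts <- numeric(nBins)
  idx <- floor(energies / binWidth) + 1
  idx <- idx[idx >= 1 & idx <= nBins]
  for (b in idx) counts[b] <- counts[b] + 1
  counts
}

# Exact canonical stick spectrum over enumerated configurations, binned
# onto a wavenumber axis: the brute-force side of the multicanonical
# reweighting comparison.
refCanonicalBinned <- function(sys, eMax, temperature, specLo, specHi,
                               specBin, slack = 100) {
  bf <- bruteForceStates(sys, eMax, cap = 5e4, slack = slack)
  kT <- kBT(temperature)
  w <- exp(-bf$energies / kT)
  w <- w / sum(w)
  nb <- round((specHi - specLo) / specBin)
  acc <- numeric(nb)
  for (k in seq_len(nrow(bf$configs))) {
    st <- stickSpectrum(sys, bf$configs[k, ], window = c(specLo, specHi))
    if (!nrow(st)) next
    idx <- floor((st$position - specLo) / specBin) + 1
    ok <- idx >= 1 & idx <= nb
    for (r in which(ok)) acc[idx[r]] <- acc[idx[r]] + w[k] * st$intensity[r]
  }
  acc
}

# Bose-Einstein mean occupation of a harmonic mode.
refBoseEinstein <- function(nu, temperature) {
  1 / (exp(nu / kBT(temperature)) - 1)
}

# Standard error of a long correlated series via block means.
blockSE <- function(x, nBlocks = 100) {
  m <- floor(length(x) / nBlocks)
  bm <- colMeans(matrix(x[seq_len(m * nBlocks)], nrow = m))
  sd(bm) / sqrt(nBlocks)
}

# Default 3-mode oracle toy for the multicanonical tests: separable
# (diagonal-only X), low closely spaced frequencies so every energy
# window is connected under single-quantum proposals and the separable
# state density is exact.
oracleToy <- function() {
  makeToyAnharmonic(nModes = 3, freqRange = c(150, 450),
                    diagRange = c(-3, -1), offScale = 0, seed = 11)
}

# The coupled variant (small off-diagonal X) for consistency checks at
# Monte-Carlo tolerance.
coupledToy <- function() {
  makeToyAnharmonic(nModes = 3, freqRange = c(150, 450),
                    diagRange = c(-3, -1), offScale = 0.1, seed = 11)
}
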