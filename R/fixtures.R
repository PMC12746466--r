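## Seeded synthetic vibrational systems and hot initial configurations.
## Every generator is a pure function of its seed (same seed, same call
## order, same output), so the whole pipeline is testable without any
## electronic-structure or experimental data. The large fixture mimics
## the *structure* of a mid-size chromophore (mode count, marker bands,
## a small active subset); none of its numbers are a real molecule's
## data.

#' Harmonic reference system
#'
#' A [VibrationalSystem-class] with X = 0 exactly; total energies are
#' \eqn{\sum_i n_i \nu_i} and all transition energies are
#' occupation-independent.
#'
#' @param freqs mode frequencies, cm\eqn{^{-1}}.
#' @param intensities base fundamental intensities (default 1).
#' @return a `VibrationalSystem`.
#' @export
makeHarmonicSystem <- function(freqs, intensities = NULL) {
  vibrationalSystem(freqs, fundIntensities = intensities)
}

#' Random small anharmonic test system
#'
#' Reproducible toy system: frequencies uniform in `freqRange`, diagonal
#' anharmonicities uniform in `diagRange` (negative), off-diagonal
#' couplings uniform in `[-offScale, 0]`. Systems whose ground-state
#' fundamentals are not all positive are redrawn (with a warning after
#' many failures). With `offScale = 0` and `diagRange = c(0, 0)` the
#' result is harmonic.
#'
#' @param nModes number of modes (default 3).
#' @param freqRange frequency range, cm\eqn{^{-1}}.
#' @param diagRange range of diagonal X (negative), cm\eqn{^{-1}}.
#' @param offScale magnitude scale of off-diagonal X, cm\eqn{^{-1}}
#'   (small relative to the diagonal).
#' @param seed integer seed.
#' @param includeWeakBands logical; when `TRUE`, assign small base
#'   intensities to overtones (5% of the fundamental) and combinations
#'   (2% of the geometric-mean fundamental) so all three band kinds are
#'   exercised.
#' @return a `VibrationalSystem`.
#' @export
makeToyAnharmonic <- function(nModes = 3, freqRange = c(400, 1000),
                              diagRange = c(-20, -5), offScale = 1,
                              seed = 1, includeWeakBands = FALSE) {
  stopifnot(nModes >= 1, freqRange[1] > 0, freqRange[1] < freqRange[2],
            diagRange[1] <= diagRange[2], diagRange[2] <= 0,
            offScale >= 0)
  set.seed(seed)
  for (try in 1:100) {
    freqs <- sort(runif(nModes, freqRange[1], freqRange[2]))
    X <- matrix(0, nModes, nModes)
    X[upper.tri(X)] <- -runif(nModes * (nModes - 1) / 2, 0, offScale)
    X <- X + t(X)
    diag(X) <- runif(nModes, diagRange[1], diagRange[2])
    iFund <- runif(nModes, 0.5, 2)
    sys <- vibrationalSystem(
      freqs, X, iFund,
      overtoneIntensities = if (includeWeakBands) 0.05 * iFund,
      combIntensities = if (includeWeakBands)
        0.02 * sqrt(outer(iFund, iFund)) * (1 - diag(nModes)))
    f0 <- .fundamentalEnergies(scaledFrequencies(sys), X, diag(X),
                               rep(0, nModes))
    if (all(f0 > 0)) return(sys)
    if (try == 100)
      warning("many draws produced non-positive ground fundamentals")
  }
  stop("could not generate a valid toy system; widen freqRange or ",
       "shrink the anharmonicities")
}

#' Large chromophore-like fixture system
#'
#' A reproducible 87-mode system structured like a mid-size conjugated
#' chromophore: frequencies span about 50-3200 cm\eqn{^{-1}}; 14
#' designated active modes (those a twisting photoisomerization would
#' energize) include two marker modes placed near 1570 cm\eqn{^{-1}}
#' (C=C-stretch-like) and 1465 cm\eqn{^{-1}} (C-C-stretch-like) that
#' dominate the mid-IR window; all diagonal anharmonicities are negative
#' and the markers couple negatively to the other active modes, so
#' cooling blue-shifts the marker bands toward their equilibrium
#' positions. Base overtone and combination intensities are small
#' fractions of the fundamentals so the spectrum carries all three band
#' kinds. Frequencies carry a 0.992 empirical scaling factor, a typical
#' calibration of calculated anharmonic frequencies against solution
#' spectra.
#'
#' @param seed integer seed (default 42).
#' @return list with `system` (a `VibrationalSystem`), `activeModes`
#'   (indices of the 14 active modes), `markerModes` (indices of the two
#'   marker modes), and `markerWindows` (named list of band windows
#'   `nu15` = 1550-1600 and `nu19` = 1440-1490 cm\eqn{^{-1}}).
#' @export
makeCyanLikeSystem <- function(seed = 42) {
  set.seed(seed)
  nTotal <- 87
  scale <- 0.992
  ## 85 background modes plus two markers; the mid-frequency draw avoids
  ## the marker windows so each window holds exactly one ground-state
  ## fundamental (its marker) by construction
  low <- sort(runif(45, 50, 900))
  mid <- sort(c(runif(22, 900, 1400), runif(6, 1680, 1780)))
  high <- sort(runif(12, 2900, 3250))
  markers <- c(1570, 1465) / scale  # placeholders, re-centred below
  freqs <- sort(c(low, mid, high, markers))
  iMark1 <- which.min(abs(freqs - markers[1]))
  iMark2 <- which.min(abs(freqs - markers[2]))
  markerModes <- c(iMark1, iMark2)

  ## 14 active modes: the two markers plus 12 low/mid-frequency modes
  pool <- setdiff(which(freqs < 1700), markerModes)
  active <- sort(c(markerModes, sample(pool, 12)))

  ## intensities: markers dominant, mid-IR background weak
  iFund <- runif(nTotal, 0.2, 4)
  iFund[iMark1] <- 120
  iFund[iMark2] <- 70

  X <- matrix(0, nTotal, nTotal)
  off <- -runif(nTotal * (nTotal - 1) / 2, 0, 0.15)
  X[upper.tri(X)] <- off
  X <- X + t(X)
  ## stronger negative couplings within the active block
  for (a in active) for (b in active) if (a < b) {
    X[a, b] <- X[b, a] <- -runif(1, 0.2, 1.2)
  }
  diag(X) <- -runif(nTotal, 2, 8)
  diag(X)[markerModes] <- -6

  ## re-centre the marker frequencies so the ground-state fundamental
  ## transition (including the anharmonic shift) lands exactly on the
  ## marker position after scaling
  for (k in 1:2) {
    i <- markerModes[k]
    shift <- 2 * X[i, i] + (sum(X[i, ]) - X[i, i]) / 2
    freqs[i] <- (c(1570, 1465)[k] - shift) / scale
  }

  otInt <- 0.03 * iFund
  cbInt <- 0.012 * sqrt(outer(iFund, iFund))
  diag(cbInt) <- 0

  sys <- vibrationalSystem(freqs, X, iFund, otInt, cbInt,
                           freqScale = scale)
  f0 <- .fundamentalEnergies(scaledFrequencies(sys), X, diag(X),
                             rep(0, nTotal))
  stopifnot(all(f0 > 0))
  list(system = sys, activeModes = active, markerModes = markerModes,
       markerWindows = list(nu15 = bandWindow(1550, 1600),
                            nu19 = bandWindow(1440, 1490)))
}

#' Generate hot initial configurations over active modes
#'
#' Distributes vibrational quanta randomly over the designated active
#' modes until the harmonic energy is within one quantum of `eTotal`
#' (spectator modes stay at zero; a thermal background can be added with
#' [sampleThermalConfig()], as [ensembleSpectra()] does per trajectory).
#' A single active mode gives the deterministic
#' `round(eTotal / nu)` quanta.
#'
#' @inheritParams totalEnergy
#' @param activeModes indices of the modes that carry the excitation.
#' @param eTotal target total (harmonic) energy, cm\eqn{^{-1}}.
#' @param nConfigs number of configurations.
#' @return integer matrix with one configuration per row
#'   (`nConfigs` x N; zero rows when `nConfigs = 0`).
#' @export
generateHotConfigs <- function(system, activeModes, eTotal, nConfigs) {
  stopifnot(eTotal > 0, nConfigs >= 0, length(activeModes) >= 1)
  N <- nModes(system)
  nu <- scaledFrequencies(system)
  if (eTotal < min(nu[activeModes]) / 2)
    stop("eTotal is below half the smallest active quantum; unreachable")
  out <- matrix(0L, nConfigs, N)
  for (k in seq_len(nConfigs)) {
    n <- integer(N)
    deficit <- eTotal
    repeat {
      elig <- activeModes[nu[activeModes] <= deficit]
      if (!length(elig)) break
      m <- if (length(elig) == 1) elig else sample(elig, 1)
      n[m] <- n[m] + 1L
      deficit <- deficit - nu[m]
    }
    ## final largest-remainder touch: one more quantum if it reduces the
    ## shortfall (gives round(), not floor(), for a single active mode)
    cand <- activeModes[which.min(abs(deficit - nu[activeModes]))]
    if (abs(deficit - nu[cand]) < abs(deficit)) {
      n[cand] <- n[cand] + 1L
    }
    out[k, ] <- n
  }
  out
}
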