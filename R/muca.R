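## Multicanonical (flat-histogram) sampling of occupation space.

#' Energy window for multicanonical sampling
#'
#' Half-open window \eqn{[e_{lo}, e_{hi})} whose width is an integer
#' multiple of the bin width, with `eLo` itself on a bin boundary so the
#' window bins align with the global density-of-states bins.
#'
#' @param eLo,eHi window bounds in cm\eqn{^{-1}} (relative to zero point).
#' @param binWidth energy bin width, cm\eqn{^{-1}} (default 16).
#' @return a list with class `"EnergyWindow"`.
#' @export
energyWindow <- function(eLo, eHi, binWidth = 16) {
  stopifnot(eLo < eHi, binWidth > 0)
  if (abs(eLo / binWidth - round(eLo / binWidth)) > 1e-9 ||
      abs((eHi - eLo) / binWidth - round((eHi - eLo) / binWidth)) > 1e-9)
    stop("window bounds must be integer multiples of binWidth")
  structure(list(eLo = eLo, eHi = eHi, binWidth = binWidth),
            class = "EnergyWindow")
}

#' Multicanonical sampling parameters
#'
#' @param r up-proposal bias; an up step is proposed with probability
#'   `r`-times that of a down step (default 1.08, which accelerates
#'   convergence of the flat-histogram walk).
#' @param alpha flatness threshold: the walk stops when every reachable
#'   histogram bin satisfies \eqn{|H_b - \langle H\rangle| / \langle
#'   H\rangle < \alpha} (default 0.25).
#' @param nWalks independent walks per window (default 6).
#' @param maxSteps safety cap on steps per walk.
#' @param spectralWindow wavenumber window for the accumulated spectra,
#'   cm\eqn{^{-1}} (default `c(1350, 1850)`).
#' @param spectralBin wavenumber bin width, cm\eqn{^{-1}} (default 1).
#' @param checkEvery flatness is tested every this many steps.
#' @return a list with class `"MucaParams"`.
#' @export
mucaParams <- function(r = 1.08, alpha = 0.25, nWalks = 6,
                       maxSteps = 2e6, spectralWindow = c(1350, 1850),
                       spectralBin = 1, checkEvery = 1000) {
  stopifnot(r > 0, alpha > 0, alpha < 1, nWalks >= 1, maxSteps >= 1,
            length(spectralWindow) == 2,
            spectralWindow[1] < spectralWindow[2], spectralBin > 0)
  structure(list(r = r, alpha = alpha, nWalks = nWalks,
                 maxSteps = maxSteps, spectralWindow = spectralWindow,
                 spectralBin = spectralBin, checkEvery = checkEvery),
            class = "MucaParams")
}

## Per-mode proposal denominator D: p_down = 1/D, p_up = r/D. D defaults
## to N but is floored at ceiling(1 + r) so the per-mode stay probability
## stays non-negative for very small systems; the Hastings ratio r^dn is
## independent of D.
.proposalDenom <- function(N, r, denom = NULL) {
  if (is.null(denom)) denom <- max(N, ceiling(1 + r))
  if ((1 + r) / denom > 1 + 1e-12)
    stop("(1 + r)/denominator exceeds 1; per-mode stay probability ",
         "would be negative")
  denom
}

#' Propose a new occupation configuration
#'
#' Each mode independently steps down one quantum with probability `1/D`,
#' up one quantum with probability `r/D`, and otherwise stays; a down draw
#' at \eqn{n_i = 0} is suppressed (treated as stay). `D` defaults to the
#' number of modes `N`, floored at `ceiling(1 + r)` so that small systems
#' remain proposable. The forward and reverse generation log-probabilities
#' of the realized move are returned for the Metropolis-Hastings ratio;
#' boundary-suppressed stays contribute identically to both, so the ratio
#' always reduces to \eqn{r^{\Delta n}} with \eqn{\Delta n} = (current
#' total quanta) - (proposed total quanta).
#'
#' @param config current occupation configuration.
#' @param r up-proposal bias.
#' @param denom optional proposal denominator `D` (default as above).
#' @return list with `config` (proposed), `deltaN` (current minus
#'   proposed total quanta), `logFwd`, `logRev`.
#' @export
proposeConfig <- function(config, r = 1.08, denom = NULL) {
  N <- length(config)
  D <- .proposalDenom(N, r, denom)
  u <- runif(N)
  down <- u < 1 / D & config > 0
  up <- u >= 1 / D & u < (1 + r) / D
  prop <- config
  prop[down] <- prop[down] - 1L
  prop[up] <- prop[up] + 1L
  ## realized-move generation probabilities (forward: n -> prop,
  ## reverse: prop -> n)
  atZeroStay <- !down & !up & config == 0
  plainStay <- !down & !up & config > 0
  logFwd <- sum(down) * log(1 / D) + sum(up) * log(r / D) +
    sum(atZeroStay) * log(1 - r / D) +
    sum(plainStay) * log(1 - (1 + r) / D)
  ## reverse: a down move is undone by an up (r/D), an up by a down (1/D,
  ## always allowed since prop > 0 there); stays are symmetric because the
  ## occupation is unchanged.
  logRev <- sum(down) * log(r / D) + sum(up) * log(1 / D) +
    sum(atZeroStay) * log(1 - r / D) +
    sum(plainStay) * log(1 - (1 + r) / D)
  list(config = prop, deltaN = sum(config) - sum(prop),
       logFwd = logFwd, logRev = logRev)
}

#' Validate a configuration against a sampling window
#'
#' A configuration is valid when its total energy lies in
#' \eqn{[e_{lo}, e_{hi})} and every fundamental transition energy out of
#' it is strictly positive (the configuration sits inside the bound-state
#' range of the Dunham expansion).
#'
#' @inheritParams totalEnergy
#' @param window an [energyWindow()].
#' @return logical.
#' @export
validateConfig <- function(system, config, window) {
  .checkConfig(system, config)
  E <- totalEnergy(system, config)
  if (E < window$eLo || E >= window$eHi) return(FALSE)
  nu <- scaledFrequencies(system)
  X <- system@xMatrix
  all(.fundamentalEnergies(nu, X, diag(X), config) > 0)
}

#' Multicanonical Metropolis-Hastings acceptance probability
#'
#' \eqn{p_{acc} = \min[1, \rho(E)/\rho(E_{prop}) \cdot r^{\Delta n}]}
#' with the densities read from the binned state counts and
#' \eqn{\Delta n} the current-minus-proposed total quanta (the Hastings
#' correction for the up-biased proposal). A proposed energy falling in a
#' bin with zero density is unreachable and is rejected.
#'
#' @param dos a [DensityOfStates-class].
#' @param E,eProp current and proposed total energies (cm\eqn{^{-1}}).
#' @param r up-proposal bias.
#' @param deltaN current minus proposed total quanta.
#' @return acceptance probability in `[0, 1]`.
#' @export
mucaAcceptance <- function(dos, E, eProp, r, deltaN) {
  w <- dos@binWidth
  nb <- length(dos@counts)
  bin <- function(e) min(max(floor(e / w) + 1, 1), nb)
  rhoE <- dos@counts[bin(E)]
  rhoP <- dos@counts[bin(eProp)]
  if (rhoP == 0) return(0)
  min(1, rhoE / rhoP * r^deltaN)
}

#' Histogram flatness test
#'
#' `TRUE` when every bin satisfies
#' \eqn{|H_b - \langle H\rangle| / \langle H\rangle < \alpha}. Callers
#' exclude unreachable (zero-density) bins before testing.
#'
#' @param H histogram counts.
#' @param alpha flatness threshold.
#' @return logical; `FALSE` when the histogram mean is zero.
#' @export
flatness <- function(H, alpha) {
  if (!length(H)) stop("H must be non-empty")
  m <- mean(H)
  if (m == 0) return(FALSE)
  all(abs(H - m) / m < alpha)
}

## Random search for a valid starting configuration inside a window:
## quanta are laid down greedily on randomly chosen modes until the
## harmonic estimate reaches a target drawn uniformly in the window, then
## the full anharmonic energy and validity are checked.
.seedConfig <- function(system, window, maxTries = 5000) {
  nu <- scaledFrequencies(system)
  N <- length(nu)
  for (k in seq_len(maxTries)) {
    target <- runif(1, window$eLo, window$eHi)
    n <- integer(N)
    deficit <- target
    repeat {
      elig <- which(nu <= deficit)
      if (!length(elig)) break
      m <- if (length(elig) == 1) elig else sample(elig, 1)
      n[m] <- n[m] + 1L
      deficit <- deficit - nu[m]
    }
    if (validateConfig(system, n, window)) return(n)
  }
  stop("no valid configuration found in window [", window$eLo, ", ",
       window$eHi, ") after ", maxTries, " tries")
}

#' Run one multicanonical walk in an energy window
#'
#' Flat-histogram walk over occupation configurations restricted to the
#' window. On every step the histogram bin of the current energy is
#' incremented and the binned stick spectrum (fundamentals, first
#' overtones, 1+1 combinations) of the current configuration is added to
#' the spectral row of that bin, regardless of acceptance. Proposals that
#' leave the window or violate \eqn{\Delta E_{fund} > 0} are rejected.
#' The walk stops when the histogram over reachable bins (bins with
#' non-zero state density) passes [flatness()] at `params$alpha`, or at
#' `params$maxSteps` with a warning.
#'
#' @inheritParams validateConfig
#' @param params a [mucaParams()].
#' @param dos a [DensityOfStates-class] binned at the window's bin width
#'   and spanning at least the window.
#' @param startConfig optional valid starting configuration (default:
#'   randomized search).
#' @param trackConfigs logical; record the visited configuration of every
#'   step (as a key string) for visitation diagnostics. Only sensible for
#'   small systems.
#' @return list with `hist` (per-window-bin visit counts), `rows`
#'   (summed binned stick spectra, one row per energy bin), `samples`
#'   (equal to `hist`), `spectralGrid` (wavenumber-bin centres),
#'   `binCenters` (energy-bin centres), `converged`, `steps`, and
#'   `visited` (character vector of config keys when tracked).
#' @export
runWalk <- function(system, window, params, dos, startConfig = NULL,
                    trackConfigs = FALSE) {
  stopifnot(inherits(window, "EnergyWindow"),
            inherits(params, "MucaParams"),
            is(dos, "DensityOfStates"))
  if (abs(dos@binWidth - window$binWidth) > 1e-9)
    stop("dos bin width must match the window bin width")
  w <- window$binWidth
  off <- round(window$eLo / w)          # global bin offset of the window
  hb <- round((window$eHi - window$eLo) / w)
  if (off + hb > length(dos@counts))
    stop("density of states does not span the window")
  reach <- dos@counts[off + seq_len(hb)] > 0
  if (!any(reach)) stop("window contains no reachable states")

  lo <- params$spectralWindow[1]
  bw <- params$spectralBin
  nb <- round((params$spectralWindow[2] - lo) / bw)
  pre <- .linePre(system)

  n <- if (is.null(startConfig)) .seedConfig(system, window)
       else startConfig
  if (!validateConfig(system, n, window))
    stop("startConfig is not valid in the window")
  E <- totalEnergy(system, n)
  curRow <- .stickRow(pre, n, lo, bw, nb)
  curBin <- floor((E - window$eLo) / w) + 1

  H <- numeric(hb)
  rows <- matrix(0, hb, nb)
  visited <- if (trackConfigs) character(params$maxSteps) else NULL
  denom <- .proposalDenom(pre$N, params$r)
  converged <- FALSE
  step <- 0L
  while (step < params$maxSteps) {
    step <- step + 1L
    H[curBin] <- H[curBin] + 1
    rows[curBin, ] <- rows[curBin, ] + curRow
    if (trackConfigs) visited[step] <- paste(n, collapse = ",")

    prop <- proposeConfig(n, params$r, denom)
    if (prop$deltaN != 0L || any(prop$config != n)) {
      if (validateConfig(system, prop$config, window)) {
        eProp <- totalEnergy(system, prop$config)
        pAcc <- mucaAcceptance(dos, E, eProp, params$r, prop$deltaN)
        if (pAcc >= 1 || runif(1) < pAcc) {
          n <- prop$config
          E <- eProp
          curRow <- .stickRow(pre, n, lo, bw, nb)
          curBin <- floor((E - window$eLo) / w) + 1
        }
      }
    }
    if (step %% params$checkEvery == 0L && flatness(H[reach],
                                                    params$alpha)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("walk reached maxSteps = ", params$maxSteps,
            " without meeting the flatness condition")
  list(hist = H, rows = rows, samples = H,
       spectralGrid = lo + (seq_len(nb) - 0.5) * bw,
       binCenters = window$eLo + (seq_len(hb) - 0.5) * w,
       converged = converged, steps = step,
       visited = if (trackConfigs) visited[seq_len(step)] else NULL)
}

#' Boltzmann reweighting of a microcanonical spectral matrix
#'
#' Normalizes each energy row by its sample count and sums rows with the
#' canonical bin weights from [boltzmannWeights()], yielding the IR stick
#' spectrum (binned) at the requested temperature. Empty rows carrying
#' more than `emptyTol` of the total Boltzmann weight trigger a warning;
#' the weights are renormalized over the populated rows.
#'
#' @param sm an energy-rowed [SpectralMatrix-class].
#' @param dos the [DensityOfStates-class] used for the sampling, binned
#'   identically.
#' @param temperature temperature in K.
#' @param emptyTol warning threshold on the total weight of empty rows.
#' @return a [Spectrum-class] of binned stick intensities on the
#'   wavenumber axis of `sm` (convolve for presentation).
#' @export
assembleCanonicalSpectrum <- function(sm, dos, temperature,
                                      emptyTol = 1e-6) {
  stopifnot(is(sm, "SpectralMatrix"), sm@rowType == "energy")
  wAll <- boltzmannWeights(dos, temperature)
  centers <- binCenters(dos)
  idx <- match(round(sm@rowAxis / dos@binWidth + 0.5),
               round(centers / dos@binWidth + 0.5))
  if (any(is.na(idx)))
    stop("spectral-matrix rows do not align with the density bins")
  wRows <- wAll[idx]
  uncovered <- sum(wAll) - sum(wRows)
  empty <- sm@samples == 0
  lost <- uncovered + sum(wRows[empty])
  if (lost > emptyTol)
    warning(sprintf(
      "%.3g of the Boltzmann weight falls on unsampled energy bins",
      lost))
  wRows[empty] <- 0
  if (sum(wRows) == 0) stop("no sampled row carries Boltzmann weight")
  wRows <- wRows / sum(wRows)
  norm <- sm@values / ifelse(sm@samples > 0, sm@samples, 1)
  Spectrum(sm@colAxis, drop(crossprod(norm, wRows)))
}

#' Simulate a canonical IR spectrum by multicanonical sampling
#'
#' Top-level driver: computes the separable-oscillator state density,
#' splits `[0, eMax)` into `nWindows` equal energy windows, runs
#' `params$nWalks` independent flat-histogram walks per window (pooling
#' their histograms and spectral rows), and Boltzmann-reweights the
#' assembled microcanonical matrix to the requested temperature.
#'
#' @inheritParams totalEnergy
#' @param temperature temperature in K.
#' @param eMax total energy range of interest, cm\eqn{^{-1}} (default
#'   about 1 eV).
#' @param nWindows number of non-overlapping energy windows (default 4).
#' @param binWidth energy bin width, cm\eqn{^{-1}} (default 16).
#' @param params a [mucaParams()].
#' @param dos optional precomputed [DensityOfStates-class] (binned at
#'   `binWidth` over at least `[0, eMax)`).
#' @param seed optional integer; when given, each walk runs under a
#'   deterministic seed derived from it.
#' @return list with `spectrum` (binned canonical stick [Spectrum-class]),
#'   `matrix` (the pooled energy-rowed [SpectralMatrix-class]), `dos`,
#'   `converged` (logical per window x walk), and `params`.
#' @export
mucaSpectrum <- function(system, temperature, eMax = 8065.54,
                         nWindows = 4, binWidth = 16,
                         params = mucaParams(), dos = NULL,
                         seed = NULL) {
  nbTot <- ceiling(eMax / binWidth)
  nbTot <- ceiling(nbTot / nWindows) * nWindows
  eTop <- nbTot * binWidth
  if (is.null(dos)) dos <- countStates(system, eTop, binWidth)
  perWin <- nbTot / nWindows

  lo <- params$spectralWindow[1]
  nb <- round((params$spectralWindow[2] - lo) / params$spectralBin)
  values <- matrix(0, nbTot, nb)
  samples <- numeric(nbTot)
  converged <- matrix(NA, nWindows, params$nWalks)
  sg <- NULL
  for (wI in seq_len(nWindows)) {
    win <- energyWindow((wI - 1) * perWin * binWidth,
                        wI * perWin * binWidth, binWidth)
    reachable <- any(dos@counts[(wI - 1) * perWin + seq_len(perWin)] > 0)
    if (!reachable) next
    for (k in seq_len(params$nWalks)) {
      if (!is.null(seed)) set.seed((seed + 7919L * wI + k) %% 2147483647L)
      walk <- runWalk(system, win, params, dos)
      rowsIdx <- (wI - 1) * perWin + seq_len(perWin)
      values[rowsIdx, ] <- values[rowsIdx, ] + walk$rows
      samples[rowsIdx] <- samples[rowsIdx] + walk$hist
      converged[wI, k] <- walk$converged
      sg <- walk$spectralGrid
    }
  }
  sm <- spectralMatrix(
    rowAxis = (seq_len(nbTot) - 0.5) * binWidth,
    colAxis = sg, values = values, samples = samples,
    rowType = "energy",
    metadata = list(params = unclass(params), seed = seed,
                    binWidth = binWidth, nWindows = nWindows))
  spec <- assembleCanonicalSpectrum(sm, dos, temperature)
  list(spectrum = spec, matrix = sm, dos = dos, converged = converged,
       params = params)
}
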