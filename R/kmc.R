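## Kinetic Monte Carlo simulation of vibrational cooling to an
## isothermal bath.

#' Kinetic Monte Carlo cooling parameters
#'
#' @param q global dimensionless rate-scaling factor (default 0.1); the
#'   single adjustable parameter of the cooling model. It scales both the
#'   downward (energy to bath) and upward (energy from bath) per-mode
#'   step probabilities and therefore affects only the rate of cooling,
#'   not the transient spectral shapes.
#' @param qi optional length-N vector of per-mode rate factors overriding
#'   `q` (mode-specific bath coupling).
#' @param dt time step in fs (default 5).
#' @param tMax trajectory length in fs.
#' @param TBath bath temperature in K (default 300); the isothermal-bath
#'   approximation holds the local solvent temperature fixed.
#' @param acceptanceMode `"as_printed"`, `"metropolis"` or `"none"`.
#'   `"as_printed"` applies \eqn{\min[1, e^{-(E - E_{prop})/k_BT}]} with
#'   the sign exactly as stated in the source formulation of this model
#'   family; `"metropolis"` uses the conventional
#'   \eqn{\min[1, e^{-(E_{prop} - E)/k_BT}]}; `"none"` accepts every
#'   proposed single-quantum move. Because the upward proposal
#'   probability already carries the Boltzmann factor
#'   \eqn{e^{-\nu_i/k_BT}}, `"none"` satisfies detailed balance exactly
#'   in the harmonic limit, whereas `"as_printed"` suppresses downward
#'   (cooling) moves of high-frequency modes by \eqn{e^{-\nu_i/k_BT}};
#'   see the package vignette for the full discussion.
#' @param nTrajectories trajectories per initial configuration
#'   (default 576).
#' @param spectralWindow,spectralBin wavenumber window and bin width of
#'   the recorded time-resolved spectra, cm\eqn{^{-1}}.
#' @return a list with class `"KmcParams"`.
#' @export
kmcParams <- function(q = 0.1, qi = NULL, dt = 5, tMax = 10000,
                      TBath = 300,
                      acceptanceMode = c("as_printed", "metropolis",
                                         "none"),
                      nTrajectories = 576,
                      spectralWindow = c(1350, 1850), spectralBin = 1) {
  stopifnot(q > 0, dt > 0, tMax >= 0, TBath > 0, nTrajectories >= 1,
            length(spectralWindow) == 2,
            spectralWindow[1] < spectralWindow[2], spectralBin > 0)
  if (!is.null(qi)) stopifnot(all(qi > 0))
  structure(list(q = q, qi = qi, dt = dt, tMax = tMax, TBath = TBath,
                 acceptanceMode = match.arg(acceptanceMode),
                 nTrajectories = nTrajectories,
                 spectralWindow = spectralWindow,
                 spectralBin = spectralBin),
            class = "KmcParams")
}

## Per-mode rate prefactor q_i * nu_i * c * dt (dimensionless) and the
## bath Boltzmann factor exp(-nu_i / kB T).
.kmcPre <- function(system, params) {
  nu <- scaledFrequencies(system)
  qi <- if (is.null(params$qi)) rep(params$q, length(nu)) else params$qi
  if (length(qi) != length(nu))
    stop("qi must have one entry per mode")
  list(a = qi * nu * .c_cm_fs * params$dt,
       bolt = exp(-nu / kBT(params$TBath)),
       kT = kBT(params$TBath))
}

#' Per-mode kinetic Monte Carlo step probabilities
#'
#' Downward: \eqn{p_{down,i} = q_i n_i \nu_i c\, dt}; upward (energy
#' gained from the bath): \eqn{p_{up,i} = q_i (n_i + 1) \nu_i c\, dt\,
#' e^{-\nu_i/k_BT}}. The product \eqn{\nu_i\, dt} is made dimensionless
#' with the speed of light (\eqn{c = 2.99792458\times 10^{-5}} cm/fs),
#' i.e. the linear frequency per femtosecond. Probabilities above 1
#' (time step too large) are clipped with a warning.
#'
#' @inheritParams totalEnergy
#' @param params a [kmcParams()].
#' @return list with numeric vectors `pDown` and `pUp`.
#' @examples
#' sys <- vibrationalSystem(1000)
#' stepProbabilities(sys, 1, kmcParams(q = 0.1, dt = 5))$pDown
#' # 0.1 * 1 * 1000 * 2.99792458e-5 * 5 = 0.01499
#' @export
stepProbabilities <- function(system, config, params) {
  .checkConfig(system, config)
  pre <- .kmcPre(system, params)
  pDown <- pre$a * config
  pUp <- pre$a * (config + 1) * pre$bolt
  if (any(pDown > 1) || any(pUp > 1)) {
    warning("step probabilities exceed 1 and were clipped; ",
            "reduce dt or q")
    pDown <- pmin(pDown, 1)
    pUp <- pmin(pUp, 1)
  }
  list(pDown = pDown, pUp = pUp)
}

## Acceptance probability of a single-quantum move with energy change
## dE = E_prop - E, under the three conventions.
.kmcAccept <- function(dE, kT, mode) {
  switch(mode,
         as_printed = min(1, exp(dE / kT)),   # e^{-(E - E_prop)/kT}
         metropolis = min(1, exp(-dE / kT)),
         none = 1)
}

#' One kinetic Monte Carlo step
#'
#' Visits the modes in random order; each mode proposes a downward or
#' upward single-quantum move with [stepProbabilities()] evaluated at the
#' configuration current at its visit (a mode's own probabilities depend
#' only on its own occupation, which is untouched until its visit).
#' Accepted moves update the energy immediately, so the acceptance of
#' later modes sees the updated configuration. Validity bounds of the
#' Dunham expansion are deliberately not enforced: hot initial
#' configurations may start outside them and must still evolve.
#'
#' @inheritParams stepProbabilities
#' @return the new occupation configuration (integer vector).
#' @export
kmcStep <- function(system, config, params) {
  .checkConfig(system, config)
  pre <- .kmcPre(system, params)
  X <- system@xMatrix
  dX <- diag(X)
  nu <- scaledFrequencies(system)
  n <- as.integer(config)
  f <- .fundamentalEnergies(nu, X, dX, n)
  pDown <- pmin(pre$a * n, 1)
  pUp <- pmin(pre$a * (n + 1) * pre$bolt, 1)
  u <- runif(length(n))
  downSel <- u < pDown
  upSel <- !downSel & u < pDown + pUp
  moving <- which(downSel | upSel)
  if (!length(moving)) return(n)
  for (m in sample(moving)) {
    delta <- if (downSel[m]) -1L else 1L
    dE <- if (delta > 0) f[m] else -(f[m] - 2 * dX[m])
    if (runif(1) < .kmcAccept(dE, pre$kT, params$acceptanceMode)) {
      n[m] <- n[m] + delta
      f <- f + delta * X[, m]
      f[m] <- f[m] + delta * dX[m]
    }
  }
  n
}

#' Run one cooling trajectory
#'
#' Evolves a configuration for `floor(tMax/dt)` steps. Before every step
#' (and once more at the final time) the current configuration is
#' recorded: its binned stick spectrum is stored in the spectral row of
#' the current time (regardless of later acceptance), and its total
#' energy is logged. Negative transition energies carry zero intensity.
#'
#' @inheritParams stepProbabilities
#' @param config0 initial occupation configuration.
#' @param recordSpectra logical; accumulate per-time binned stick spectra
#'   (turn off for pure occupation statistics, e.g. very long
#'   equilibrium runs).
#' @param returnConfigs logical; also return the full occupation history
#'   (steps+1 x N matrix).
#' @return list with `times` (fs), `energies` (cm\eqn{^{-1}}),
#'   `totalQuanta`, `rows` (time x wavenumber matrix or `NULL`),
#'   `spectralGrid`, `finalConfig`, and `configs` (when requested).
#' @export
runTrajectory <- function(system, config0, params,
                          recordSpectra = TRUE, returnConfigs = FALSE) {
  .checkConfig(system, config0)
  pre <- .kmcPre(system, params)
  lp <- .linePre(system)
  X <- system@xMatrix
  dX <- lp$dX
  nSteps <- floor(params$tMax / params$dt)
  nRec <- nSteps + 1L
  lo <- params$spectralWindow[1]
  bw <- params$spectralBin
  nb <- round((params$spectralWindow[2] - lo) / bw)

  n <- as.integer(config0)
  N <- length(n)
  E <- totalEnergy(system, n)
  f <- .fundamentalEnergies(lp$nu, X, dX, n)
  rows <- if (recordSpectra) matrix(0, nRec, nb) else NULL
  energies <- numeric(nRec)
  quanta <- numeric(nRec)
  configs <- if (returnConfigs) matrix(0L, nRec, N) else NULL
  clipped <- FALSE
  rowDirty <- TRUE
  curRow <- NULL
  aMode <- params$acceptanceMode
  kT <- pre$kT

  for (k in seq_len(nRec)) {
    if (recordSpectra) {
      if (rowDirty) {
        ln <- .allLines(lp, n, f)
        curRow <- .binLines(ln$position, ln$intensity, lo, bw, nb)
        rowDirty <- FALSE
      }
      rows[k, ] <- curRow
    }
    energies[k] <- E
    quanta[k] <- sum(n)
    if (returnConfigs) configs[k, ] <- n
    if (k > nSteps) break

    pDown <- pre$a * n
    pUp <- pre$a * (n + 1) * pre$bolt
    if (!clipped && (any(pDown > 1) || any(pUp > 1))) {
      warning("step probabilities exceed 1 and were clipped; ",
              "reduce dt or q")
      clipped <- TRUE
    }
    if (clipped) {
      pDown <- pmin(pDown, 1)
      pUp <- pmin(pUp, 1)
    }
    u <- runif(N)
    downSel <- u < pDown
    upSel <- !downSel & u < pDown + pUp
    moving <- which(downSel | upSel)
    if (length(moving)) {
      if (length(moving) > 1L) moving <- sample(moving)
      for (m in moving) {
        delta <- if (downSel[m]) -1L else 1L
        dE <- if (delta > 0) f[m] else -(f[m] - 2 * dX[m])
        acc <- if (aMode == "none") TRUE
               else if (aMode == "as_printed") {
                 dE >= 0 || runif(1) < exp(dE / kT)
               } else {
                 dE <= 0 || runif(1) < exp(-dE / kT)
               }
        if (acc) {
          n[m] <- n[m] + delta
          E <- E + dE
          f <- f + delta * X[, m]
          f[m] <- f[m] + delta * dX[m]
          rowDirty <- TRUE
        }
      }
    }
  }
  list(times = (seq_len(nRec) - 1L) * params$dt,
       energies = energies, totalQuanta = quanta, rows = rows,
       spectralGrid = lo + (seq_len(nb) - 0.5) * bw,
       finalConfig = n, configs = configs)
}

#' Ensemble-averaged time-resolved spectra
#'
#' Runs `params$nTrajectories` cooling trajectories for every initial
#' configuration and averages the per-time spectral rows over all
#' trajectories and configurations. When `thermalT > 0`, a fresh thermal
#' configuration sampled at that temperature is added element-wise to the
#' initial configuration of every trajectory (the molecule's pre-existing
#' thermal occupation), resampled per trajectory.
#'
#' @inheritParams stepProbabilities
#' @param initialConfigs matrix with one initial configuration per row
#'   (or a single configuration vector).
#' @param thermalT temperature (K) of the added thermal background, or 0
#'   to disable.
#' @param seed optional integer for deterministic per-trajectory seeding.
#' @return a time-rowed [SpectralMatrix-class]; `samples` is the number
#'   of accumulated trajectories, and `smMetadata()$meanEnergy` carries
#'   the ensemble-mean total energy at each time.
#' @export
ensembleSpectra <- function(system, initialConfigs, params,
                            thermalT = 300, seed = NULL) {
  if (is.null(dim(initialConfigs)))
    initialConfigs <- matrix(initialConfigs, nrow = 1)
  nCfg <- nrow(initialConfigs)
  stopifnot(nCfg >= 1)
  nSteps <- floor(params$tMax / params$dt)
  nRec <- nSteps + 1L
  nb <- round((params$spectralWindow[2] - params$spectralWindow[1]) /
                params$spectralBin)
  values <- matrix(0, nRec, nb)
  eSum <- numeric(nRec)
  total <- 0L
  sg <- NULL
  for (ci in seq_len(nCfg)) {
    for (j in seq_len(params$nTrajectories)) {
      if (!is.null(seed))
        set.seed((seed + 104729L * ci + j) %% 2147483647L)
      n0 <- initialConfigs[ci, ]
      if (thermalT > 0)
        n0 <- n0 + sampleThermalConfig(system, thermalT)
      tr <- runTrajectory(system, n0, params, recordSpectra = TRUE)
      values <- values + tr$rows
      eSum <- eSum + tr$energies
      total <- total + 1L
      sg <- tr$spectralGrid
    }
  }
  spectralMatrix(
    rowAxis = (seq_len(nRec) - 1L) * params$dt,
    colAxis = sg, values = values, samples = rep(total, nRec),
    rowType = "time",
    metadata = list(params = unclass(params), seed = seed,
                    meanEnergy = eSum / total,
                    nConfigs = nCfg))
}

#' Difference spectra against an equilibrium reference
#'
#' Subtracts a reference (e.g. 300 K equilibrium) spectrum from every
#' normalized time row, producing the bleach-plus-growth representation
#' of a transient-absorption experiment.
#'
#' @param sm a time-rowed [SpectralMatrix-class].
#' @param reference a [Spectrum-class] on the same wavenumber axis.
#' @return a [SpectralMatrix-class] of difference rows (samples all 1).
#' @export
differenceSpectra <- function(sm, reference) {
  stopifnot(is(sm, "SpectralMatrix"), is(reference, "Spectrum"))
  if (length(reference@grid) != length(sm@colAxis) ||
      max(abs(reference@grid - sm@colAxis)) > 1e-6)
    stop("reference grid does not match the spectral-matrix columns")
  norm <- sm@values / ifelse(sm@samples > 0, sm@samples, 1)
  diffs <- sweep(norm, 2, reference@values, "-")
  spectralMatrix(sm@rowAxis, sm@colAxis, diffs,
                 samples = rep(1, length(sm@rowAxis)),
                 rowType = "time",
                 metadata = c(sm@metadata, list(difference = TRUE)))
}
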